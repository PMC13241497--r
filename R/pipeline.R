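#' Pipeline configuration
#'
#' Collects every threshold of the analysis chain, all defaulting to the
#' values of the underlying protocol: 36-slot 09:00--18:00 window, 4th-order
#' 20 Hz Butterworth low-pass, slot coverage 0.75, inclusion rules
#' (>= 4 simultaneous slots/day, >= 3 days/participant, >= 9 h sensor
#' time/day), half-slot diary overlap rule.
#'
#' @param input_dir Directory with input CSVs (epoch bundle written by
#'   [write_bundle()] or raw \code{<participant>_<date>_<position>.csv}
#'   files plus \code{diary.csv}, \code{compendium.csv},
#'   \code{metadata.csv}).
#' @param input_kind \code{"epochs"} (default) or \code{"raw"}.
#' @param out_dir Output directory (optional; results returned either way).
#' @param window A [day_window].
#' @param filter_cfg A [filter_config] (raw ingestion only).
#' @param min_coverage Slot coverage threshold.
#' @param rules A [qc_rules].
#' @param overlap_rule Diary slot-membership rule.
#' @param optimizer An [optimizer_config].
#' @param tremor_positions Positions reported in the tremor stratification.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input_dir = NULL, input_kind = c("epochs", "raw"),
                            out_dir = NULL, window = day_window(),
                            filter_cfg = filter_config(),
                            min_coverage = 0.75, rules = qc_rules(window = window),
                            overlap_rule = c("half", "any"),
                            optimizer = optimizer_config(),
                            tremor_positions = c("wrist", "lower_back"),
                            seed = 1L) {
  input_kind <- match.arg(input_kind)
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(min_coverage >= 0, min_coverage <= 1)
  structure(list(input_dir = input_dir, input_kind = input_kind,
                 out_dir = out_dir, window = window, filter_cfg = filter_cfg,
                 min_coverage = min_coverage, rules = rules,
                 overlap_rule = overlap_rule, optimizer = optimizer,
                 tremor_positions = tremor_positions, seed = as.integer(seed)),
            class = "pipeline_config")
}

stop_actidiary <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the agreement analysis on an in-memory bundle
#'
#' Executes the stages in order: slot aggregation of the sensor arm, diary
#' parsing and MET slot mapping, day-level QC, cohort assembly per sensor and
#' MET level, Min-Max normalization (ENMO per sensor; the three MET levels
#' jointly), group-mean profiling, Nelder-Mead fitting of the nine correction
#' factors, per-participant RMSE, summary tables, and (when metadata is
#' present) the tremor stratification.
#'
#' @param bundle A \code{synth_bundle} or equivalent list with
#'   \code{epochs} (or \code{raw}), \code{diary}, \code{compendium} and
#'   optionally \code{metadata}.
#' @param cfg A [pipeline_config].
#' @return An \code{actidiary_run} list with elements \code{scaling}
#'   (9-row data frame), \code{subject_rmse}, \code{summary},
#'   \code{tremor_summary}, \code{profiles}, \code{qc}, \code{panels},
#'   \code{norm_params}, \code{exclusions}, \code{totals}.
#' @export
run_agreement <- function(bundle, cfg = pipeline_config()) {
  w <- cfg$window
  # --- stage 1: sensor arm -> slots ---------------------------------------
  epochs <- bundle$epochs
  if (is.null(epochs)) {
    if (is.null(bundle$raw))
      stop_actidiary("run_agreement: bundle has neither epochs nor raw data",
                     "actidiary_data_error")
    epochs <- lapply(bundle$raw, function(r)
      aggregate_5s(compute_enmo(r, cfg$filter_cfg)))
  }
  enmo_days <- lapply(epochs, aggregate_slots, window = w,
                      min_coverage = cfg$min_coverage)
  spans <- lapply(epochs, sensor_day_span)
  # --- stage 2: diary arm -> MET slots ------------------------------------
  parsed <- parse_diary(bundle$diary)
  ents <- parsed$entries
  diary_keys <- unique(paste(ents$participant, ents$date, sep = "|"))
  met_days <- list()
  for (key in diary_keys) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- ents[ents$participant == p[1] & ents$date == p[2], , drop = FALSE]
    ms <- diary_to_slots(sub, bundle$compendium, window = w,
                         overlap_rule = cfg$overlap_rule)
    attr(ms, "participant") <- p[1]; attr(ms, "date") <- p[2]
    met_days[[key]] <- ms
  }
  empty_met <- diary_to_slots(ents[0, , drop = FALSE], bundle$compendium,
                              window = w, overlap_rule = cfg$overlap_rule)
  # --- stage 3: day-level QC ----------------------------------------------
  day_records <- vector("list", length(enmo_days))
  keys <- names(enmo_days)
  for (j in seq_along(keys)) {
    p <- strsplit(keys[j], "|", fixed = TRUE)[[1]]
    pd_key <- paste(p[1], p[2], sep = "|")
    md <- met_days[[pd_key]]
    if (is.null(md)) { md <- empty_met; attr(md, "n_entries") <- 0L }
    day_records[[j]] <- validate_day(enmo_days[[j]], md, spans[[j]],
                                     rules = cfg$rules, participant = p[1],
                                     date = p[2], position = p[3])
  }
  # --- stage 4: cohort panels ---------------------------------------------
  levels_ <- c("low", "avg", "high")
  panels <- list()
  for (pos in sensor_positions()) for (lv in levels_) {
    panels[[paste(pos, lv, sep = "|")]] <- tryCatch(
      build_cohort(day_records, pos, lv, cfg$rules),
      error = function(e) stop_actidiary(
        sprintf("cohort_qc: %s", conditionMessage(e)),
        "actidiary_empty_cohort"))
  }
  # --- stage 5: normalization ---------------------------------------------
  norm_enmo <- list()
  for (pos in sensor_positions())
    norm_enmo[[pos]] <- fit_minmax(panels[[paste(pos, "low", sep = "|")]]$enmo)
  met_pool <- unique(do.call(rbind, lapply(names(panels), function(k) {
    pn <- panels[[k]]
    data.frame(participant = pn$participant, date = pn$date,
               slot_index = pn$slot_index,
               level = attr(pn, "met_level"), met = pn$met,
               stringsAsFactors = FALSE)
  })))
  norm_met <- fit_minmax(met_pool$met)
  for (k in names(panels)) {
    pos <- strsplit(k, "|", fixed = TRUE)[[1]][1]
    panels[[k]]$enmo <- apply_minmax(panels[[k]]$enmo, norm_enmo[[pos]])
    panels[[k]]$met <- apply_minmax(panels[[k]]$met, norm_met)
    rng <- range(panels[[k]]$enmo, panels[[k]]$met)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)   # hard normalization invariant
      stop_actidiary(sprintf("normalized panel %s outside [0,1]", k),
                     "actidiary_data_error")
  }
  # --- stages 6-7: profiles, alpha fits, subject RMSE ---------------------
  profiles <- list(); scalings <- list(); rmse_rows <- list()
  for (k in names(panels)) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    pn <- panels[[k]]
    pe <- group_profile(pn, "enmo", n_slots = w$n_slots)
    pm <- group_profile(pn, "met", n_slots = w$n_slots)
    profiles[[k]] <- list(enmo = pe, met = pm)
    sc <- fit_alpha(pe, pm, cfg$optimizer, sensor_position = p[1],
                    met_level = p[2])
    scalings[[k]] <- sc
    rmse_rows[[k]] <- subject_rmse(pn, sc)
  }
  scaling_df <- do.call(rbind, lapply(scalings, function(s)
    data.frame(sensor_position = s$sensor_position, met_level = s$met_level,
               alpha = s$alpha, init_alpha = s$init_alpha,
               fit_rmse = s$fit_rmse, n_slots_used = s$n_slots_used,
               converged = s$converged, stringsAsFactors = FALSE)))
  rownames(scaling_df) <- NULL
  agreements <- do.call(rbind, rmse_rows)
  rownames(agreements) <- NULL
  # --- stage 8: summaries & tremor ----------------------------------------
  summary_df <- summarize_rmse(agreements)
  tremor_df <- NULL
  if (!is.null(bundle$metadata)) {
    labels <- tremor_label(bundle$metadata$participant,
                           bundle$metadata$tremor_sum)
    tremor_df <- tremor_split(labels, agreements,
                              positions = cfg$tremor_positions)
  }
  qc <- qc_report(day_records)
  totals <- list(
    n_day_records = nrow(qc),
    n_included_days = sum(qc$included),
    n_participants = lapply(panels, attr, "n_participants"),
    n_epochs = vapply(panels, nrow, integer(1)))
  run <- structure(list(config = cfg, scaling = scaling_df,
                        subject_rmse = agreements, summary = summary_df,
                        tremor_summary = tremor_df, profiles = profiles,
                        qc = qc, panels = panels,
                        norm_params = list(enmo = norm_enmo, met = norm_met),
                        totals = totals),
                   class = "actidiary_run")
  if (!is.null(cfg$out_dir)) write_reports(run, cfg$out_dir)
  run
}

#' Run the full pipeline from a configuration
#'
#' Disk-based entry point: reads the input bundle named by
#' \code{cfg$input_dir} (epoch CSVs, or raw accelerometer CSVs with
#' \code{input_kind = "raw"}), runs [run_agreement()], and writes reports to
#' \code{cfg$out_dir} when set.
#'
#' @param cfg A [pipeline_config] with \code{input_dir} set.
#' @return An \code{actidiary_run}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$input_dir))
    stop_actidiary("run_pipeline: input_dir not set", "actidiary_data_error")
  bundle <- if (cfg$input_kind == "epochs") read_bundle(cfg$input_dir)
  else read_raw_bundle(cfg$input_dir)
  run_agreement(bundle, cfg)
}

read_raw_bundle <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!basename(files) %in%
                   c("diary.csv", "compendium.csv", "metadata.csv",
                     "ground_truth_schedule.csv")]
  files <- files[!grepl("^enmo5s_", basename(files))]
  if (!length(files))
    stop_actidiary(sprintf("read_raw_bundle: no raw CSVs in %s", dir),
                   "actidiary_data_error")
  raw <- list()
  for (f in files) {
    r <- read_raw_accel_csv(f)
    raw[[paste(r$participant_id, r$date, r$sensor_position, sep = "|")]] <- r
  }
  diary <- utils::read.csv(file.path(dir, "diary.csv"),
                           stringsAsFactors = FALSE)
  compendium <- read_compendium(file.path(dir, "compendium.csv"))
  meta_path <- file.path(dir, "metadata.csv")
  metadata <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  list(raw = raw, diary = diary, compendium = compendium, metadata = metadata)
}

#' Write run reports
#'
#' Persists the run as tidy CSVs (scaling results, per-participant RMSE,
#' Table-1-layout summary, tremor stratification, per-slot group profiles,
#' QC report) plus a machine-readable \code{run_summary.json} carrying the
#' nine fitted correction factors, exclusion tallies and cohort totals, and
#' the resolved configuration (\code{config.yaml}) for provenance.
#'
#' @param run An \code{actidiary_run}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_reports <- function(run, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("write_reports: cannot create %s", out_dir),
                call. = FALSE)
  utils::write.csv(run$scaling, file.path(out_dir, "scaling_results.csv"),
                   row.names = FALSE)
  utils::write.csv(run$subject_rmse, file.path(out_dir, "subject_rmse.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "summary_table1.csv"),
                   row.names = FALSE)
  if (!is.null(run$tremor_summary))
    utils::write.csv(run$tremor_summary,
                     file.path(out_dir, "tremor_summary.csv"),
                     row.names = FALSE)
  prof <- do.call(rbind, lapply(names(run$profiles), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    pe <- run$profiles[[k]]$enmo; pm <- run$profiles[[k]]$met
    data.frame(sensor_position = p[1], met_level = p[2],
               slot_index = pe$slot_index,
               enmo_mean = pe$mean, enmo_sd = pe$sd,
               met_mean = pm$mean, met_sd = pm$sd,
               n_participants = pe$n_participants, stringsAsFactors = FALSE)
  }))
  utils::write.csv(prof, file.path(out_dir, "group_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(run$qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  excl <- table(run$qc$exclusion_reason[!run$qc$included])
  summary_json <- list(
    alphas = stats::setNames(as.list(run$scaling$alpha),
                             paste(run$scaling$sensor_position,
                                   run$scaling$met_level, sep = ".")),
    totals = list(n_day_records = run$totals$n_day_records,
                  n_included_days = run$totals$n_included_days,
                  n_epochs = as.list(run$totals$n_epochs)),
    exclusion_tallies = as.list(excl),
    normalization = list(
      enmo = lapply(run$norm_params$enmo, function(p)
        list(min = p$min, max = p$max)),
      met = list(min = run$norm_params$met$min,
                 max = run$norm_params$met$max)))
  jsonlite::write_json(summary_json, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  cfg_list <- list(
    input_dir = cfg$input_dir, input_kind = cfg$input_kind,
    out_dir = cfg$out_dir,
    window = list(start = format_tod(cfg$window$start),
                  end = format_tod(cfg$window$end),
                  slot_s = cfg$window$slot_s),
    filter = unclass(cfg$filter_cfg), min_coverage = cfg$min_coverage,
    rules = list(min_simultaneous = cfg$rules$min_simultaneous,
                 min_days = cfg$rules$min_days,
                 min_sensor_hours = cfg$rules$min_sensor_hours,
                 hours_mode = cfg$rules$hours_mode),
    overlap_rule = cfg$overlap_rule,
    optimizer = unclass(cfg$optimizer), seed = cfg$seed)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.actidiary_run <- function(x, ...) {
  cat("<actidiary_run>\n")
  cat(sprintf("  days: %d records, %d included\n", x$totals$n_day_records,
              x$totals$n_included_days))
  cat("  correction factors:\n")
  s <- x$scaling
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-10s %-4s alpha = %.4f (fit RMSE %.4f)\n",
                s$sensor_position[i], s$met_level[i], s$alpha[i],
                s$fit_rmse[i]))
  invisible(x)
}
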