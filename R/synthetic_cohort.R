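#' Synthetic cohort configuration
#'
#' Describes the stated world of the generator: a drug-naive PD-like cohort
#' wearing three synchronized sensors over daytime recordings, with activity
#' diaries mirroring the latent schedule. Every pipeline quantity has a known
#' ground truth, so the whole analysis chain is testable without study data.
#'
#' The latent state of a 15-minute slot is an activity-context intensity
#' \eqn{u \in [0, 1]}. Diary MET values are constructed so that, after joint
#' Min-Max normalization, the normalized level-L MET equals
#' \code{alpha_true[L]} times the normalized ENMO of an ideal sensor: each
#' context carries two parallel diary activities (equal duration) whose METs
#' are \code{met_floor + span * alpha_true["low"] * u} and
#' \code{met_floor + span * alpha_true["high"] * u}. Because both arms are
#' Min-Max scaled, this construction requires \code{alpha_true["high"] == 1}
#' and \code{alpha_true["avg"]} equal to the midpoint of low and high; other
#' values are rejected (they would not be recoverable truths).
#'
#' \code{sensor_gain} is a response-shape exponent: a sensor's epoch ENMO is
#' \code{sensor_amp * u^(1/gain)}. Any purely multiplicative gain would
#' cancel in Min-Max scaling; an exponent > 1 inflates amplitudes at
#' submaximal intensities (the wrist phenomenon) and provably lowers the
#' fitted correction factor. \code{sensor_amp} carries the raw g-unit scale
#' (wrist > ankle ~ lower back), which normalization removes.
#'
#' @param n_participants,days_per_participant Cohort dimensions (defaults 25
#'   and 5).
#' @param window Analysis [day_window] (default 09:00--18:00).
#' @param record_start,record_end Recorded span per day, seconds since
#'   midnight (default 08:30--18:30: devices worn over the waking day, so a
#'   9 h covered-time rule survives small wear gaps).
#' @param sensor_amp Named amplitude per position in g.
#' @param sensor_gain Named response-shape exponent per position (wrist
#'   default 1.25 > 1).
#' @param alpha_true Named true correction factors per MET level; high must
#'   be 1 and avg the low/high midpoint (see Details).
#' @param noise_sd SD of additive white noise per 5-second epoch, in units of
#'   the sensor's dynamic range (normalized scale).
#' @param wear_gap_rate Probability that any 15-minute span of the recorded
#'   day is a non-wear gap (sensor epochs dropped; in-window gaps also emit a
#'   diary non-wear entry).
#' @param tremor_fraction Fraction of participants in the stronger-tremor
#'   stratum (tremor item sum > 1); default 11/25.
#' @param tremor_amplitude Additional wrist ENMO per epoch (g) per unit of
#'   severity for stronger-tremor participants (default 0.03).
#' @param tremor_freq_hz Tremor band for raw-signal synthesis (default 4--6).
#' @param met_floor,met_ceiling MET range of the activity catalogue
#'   (defaults 1 and 8).
#' @param seed Integer RNG seed; the bundle is bit-identical under a fixed
#'   seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_participants = 25L, days_per_participant = 5L,
                         window = day_window(),
                         record_start = parse_tod("08:30"),
                         record_end = parse_tod("18:30"),
                         sensor_amp = c(ankle = 0.06, wrist = 0.09,
                                        lower_back = 0.05),
                         sensor_gain = c(ankle = 1, wrist = 1.25,
                                         lower_back = 1),
                         alpha_true = c(low = 0.7, avg = 0.85, high = 1),
                         noise_sd = 0.05, wear_gap_rate = 0.05,
                         tremor_fraction = 11 / 25, tremor_amplitude = 0.03,
                         tremor_freq_hz = c(4, 6),
                         met_floor = 1, met_ceiling = 8, seed = 1L) {
  stopifnot(n_participants >= 1, days_per_participant >= 1,
            inherits(window, "day_window"),
            record_start <= window$start, record_end >= window$end,
            all(sensor_positions() %in% names(sensor_amp)),
            all(sensor_positions() %in% names(sensor_gain)),
            all(sensor_amp > 0), all(sensor_gain > 0),
            noise_sd >= 0, wear_gap_rate >= 0, wear_gap_rate <= 1,
            tremor_fraction >= 0, tremor_fraction <= 1,
            tremor_amplitude >= 0, met_ceiling > met_floor)
  a <- alpha_true
  if (!all(c("low", "avg", "high") %in% names(a)) || any(a <= 0))
    stop("alpha_true must be positive and named low/avg/high", call. = FALSE)
  if (abs(a[["high"]] - 1) > 1e-12)
    stop(paste("alpha_true['high'] must be 1: both arms are Min-Max scaled",
               "to [0,1], so the largest level factor is not identifiable",
               "away from 1"), call. = FALSE)
  if (abs(a[["avg"]] - (a[["low"]] + a[["high"]]) / 2) > 1e-9)
    stop(paste("alpha_true['avg'] must be the low/high midpoint: the average",
               "MET of two equal-duration parallel activities is their mean"),
         call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 days_per_participant = as.integer(days_per_participant),
                 window = window, record_start = record_start,
                 record_end = record_end, sensor_amp = sensor_amp,
                 sensor_gain = sensor_gain, alpha_true = a,
                 noise_sd = noise_sd, wear_gap_rate = wear_gap_rate,
                 tremor_fraction = tremor_fraction,
                 tremor_amplitude = tremor_amplitude,
                 tremor_freq_hz = tremor_freq_hz,
                 met_floor = met_floor, met_ceiling = met_ceiling,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Activity-context catalogue: latent intensity u plus two parallel diary
# activities whose METs are floor + span*alpha*u for the low and high factor.
# Labels are synthetic; MET values are derived, not quoted from any source.
synth_catalogue <- function(cfg) {
  u <- c(0, 0.06, 0.12, 0.2, 0.28, 0.4, 0.55, 0.75, 1)
  label_a <- c("resting", "watching television", "reading", "eating",
               "cooking", "housekeeping", "gardening", "shopping", "cycling")
  label_b <- c("sitting quietly", "knitting", "desk work",
               "light conversation", "washing dishes", "ironing",
               "walking slow", "walking brisk", "stair climbing")
  intensity <- cut(u, c(-Inf, 1 / 3, 2 / 3, Inf),
                   labels = c("mild", "moderate", "vigorous"))
  span <- cfg$met_ceiling - cfg$met_floor
  met_a <- cfg$met_floor + span * cfg$alpha_true[["low"]] * u
  met_b <- cfg$met_floor + span * cfg$alpha_true[["high"]] * u
  list(u = u, label_a = label_a, label_b = label_b,
       intensity = as.character(intensity), met_a = met_a, met_b = met_b)
}

# Compendium CSV content implied by the catalogue.
synth_compendium <- function(cfg) {
  cat_ <- synth_catalogue(cfg)
  df <- data.frame(
    activity = c(cat_$label_a, cat_$label_b),
    intensity = rep(cat_$intensity, 2),
    code = sprintf("syn%05d", seq_len(2 * length(cat_$u)) + 90000L),
    met = c(cat_$met_a, cat_$met_b),
    stringsAsFactors = FALSE)
  class(df) <- c("compendium_table", "data.frame")
  df
}

participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 40503) %% 2147483647)
}

#' Generate a synthetic cohort bundle
#'
#' Fast path (default): emits 5-second ENMO epoch series directly, skipping
#' 100 Hz raw synthesis -- the pipeline consumes ENMO statistics, not gait
#' kinematics. With \code{raw = TRUE}, raw tri-axial recordings are
#' synthesized per slot via [synthesize_raw_segment()] (reserved for small
#' configurations; a full default-size day is ~3.6 million samples per
#' sensor).
#'
#' @param cfg A [synth_config].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   CSV files (epoch or raw series per participant-day-sensor, diary,
#'   Compendium table, metadata) plus \code{ground_truth.json}.
#' @param raw Synthesize raw 100 Hz recordings instead of epoch series.
#' @return A \code{synth_bundle} list: \code{epochs} (named
#'   \code{"pid|date|position"} list of \code{enmo_epochs} data frames; or
#'   \code{raw} recordings when \code{raw = TRUE}), \code{diary},
#'   \code{compendium}, \code{metadata} (participant, tremor_sum), and
#'   \code{ground_truth} (per-slot latent schedule, \code{alpha_true}, config
#'   echo).
#' @export
synthesize_cohort <- function(cfg = synth_config(), out_dir = NULL,
                              raw = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  cat_ <- synth_catalogue(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_participants
  pids <- sprintf("P%02d", seq_len(n))
  dates <- as.character(as.Date("2024-03-04") +
                          seq_len(cfg$days_per_participant) - 1L)
  # tremor stratum assignment
  n_strong <- round(cfg$tremor_fraction * n)
  strong <- sample(n, n_strong)
  tremor_sum <- integer(n)
  tremor_sum[strong] <- sample(2:6, n_strong, replace = TRUE)
  tremor_sum[-strong] <- sample(0:1, n - n_strong, replace = TRUE,
                                prob = c(0.36, 0.64))
  if (!n_strong) tremor_sum <- sample(0:1, n, replace = TRUE,
                                      prob = c(0.36, 0.64))
  propensity <- stats::runif(n, 0.15, 0.55)

  w <- cfg$window
  epoch_s <- 5
  rec_slots <- seq(cfg$record_start, cfg$record_end - w$slot_s, by = w$slot_s)
  n_rec_slots <- length(rec_slots)
  in_window <- rec_slots >= w$start & rec_slots < w$end
  epochs_per_slot <- w$slot_s / epoch_s

  epochs <- list()
  raw_recs <- list()
  diary_rows <- list()
  sched_rows <- list()

  for (i in seq_len(n)) {
    set.seed(participant_seed(cfg$seed, i))
    sev <- if (tremor_sum[i] >= 2) tremor_sum[i] / 4 else 0
    for (d in seq_along(dates)) {
      # --- latent schedule on the analysis window -------------------------
      ctx <- integer(0)
      filled <- 0L
      while (filled < w$n_slots) {
        len <- min(sample(1:6, 1), w$n_slots - filled)
        frac <- (filled + len / 2) / w$n_slots
        mu <- propensity[i] + 0.15 * sin(pi * frac)   # midday bump
        wt <- exp(-(cat_$u - mu)^2 / (2 * 0.3^2))
        k <- sample(length(cat_$u), 1, prob = wt)
        ctx <- c(ctx, rep(k, len))
        filled <- filled + len
      }
      if (!any(ctx == 1L)) {      # guarantee a rest block (u = 0) per day
        b1 <- seq_len(which(c(diff(ctx) != 0, TRUE))[1])
        ctx[b1] <- 1L
      }
      u_slot_win <- cat_$u[ctx]
      # wear gaps over the full recorded span
      gap <- stats::runif(n_rec_slots) < cfg$wear_gap_rate
      # --- diary entries (two parallel activities per block) --------------
      blocks <- rle(ctx)
      b_end <- cumsum(blocks$lengths)
      b_start <- b_end - blocks$lengths
      for (b in seq_along(blocks$values)) {
        k <- blocks$values[b]
        s0 <- w$start + b_start[b] * w$slot_s
        s1 <- w$start + b_end[b] * w$slot_s
        diary_rows[[length(diary_rows) + 1L]] <- data.frame(
          participant = pids[i], date = dates[d],
          start = format_tod(c(s0, s0)), end = format_tod(c(s1, s1)),
          activity = c(cat_$label_a[k], cat_$label_b[k]),
          intensity = rep(cat_$intensity[k], 2),
          non_wear = FALSE, comment = "", stringsAsFactors = FALSE)
      }
      gap_in_win <- which(gap & in_window)
      for (g in gap_in_win) {
        diary_rows[[length(diary_rows) + 1L]] <- data.frame(
          participant = pids[i], date = dates[d],
          start = format_tod(rec_slots[g]),
          end = format_tod(rec_slots[g] + w$slot_s),
          activity = "non-wear", intensity = "",
          non_wear = TRUE, comment = "device off", stringsAsFactors = FALSE)
      }
      sched_rows[[length(sched_rows) + 1L]] <- data.frame(
        participant = pids[i], date = dates[d],
        slot_index = seq(0L, w$n_slots - 1L), context = ctx,
        u = u_slot_win, gapped = gap[in_window], stringsAsFactors = FALSE)
      # --- sensor series ---------------------------------------------------
      u_rec <- rep(0, n_rec_slots)       # outside the window: resting
      u_rec[in_window] <- u_slot_win
      keep_slot <- !gap
      for (pos in sensor_positions()) {
        amp <- cfg$sensor_amp[[pos]]
        gain <- cfg$sensor_gain[[pos]]
        key <- paste(pids[i], dates[d], pos, sep = "|")
        if (raw) {
          raw_recs[[key]] <- synth_raw_day(
            pids[i], pos, dates[d], rec_slots[keep_slot],
            u_rec[keep_slot], amp, gain, w$slot_s, cfg,
            tremor = if (pos == "wrist") sev else 0)
        } else {
          resp <- amp * u_rec^(1 / gain)
          val <- rep(resp, each = epochs_per_slot)
          if (cfg$noise_sd > 0)
            val <- val + amp * stats::rnorm(length(val), 0, cfg$noise_sd)
          if (pos == "wrist" && sev > 0 && cfg$tremor_amplitude > 0)
            val <- val + cfg$tremor_amplitude * sev *
              stats::runif(length(val), 0.5, 1.5)
          keep_ep <- rep(keep_slot, each = epochs_per_slot)
          starts <- rep(rec_slots, each = epochs_per_slot) +
            epoch_s * (seq_len(epochs_per_slot) - 1)
          ep <- data.frame(epoch_start = starts[keep_ep],
                           enmo_mean = pmax(val[keep_ep], 0),
                           n_samples = 500L)
          class(ep) <- c("enmo_epochs", "data.frame")
          epochs[[key]] <- ep
        }
      }
    }
  }

  bundle <- structure(list(
    config = cfg,
    epochs = if (!raw) epochs,
    raw = if (raw) raw_recs,
    diary = do.call(rbind, diary_rows),
    compendium = synth_compendium(cfg),
    metadata = data.frame(participant = pids, tremor_sum = tremor_sum,
                          stringsAsFactors = FALSE),
    ground_truth = list(alpha_true = as.list(cfg$alpha_true),
                        sensor_gain = as.list(cfg$sensor_gain),
                        schedule = do.call(rbind, sched_rows),
                        tremor_sum = stats::setNames(tremor_sum, pids),
                        seed = cfg$seed)),
    class = "synth_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# One raw day from per-slot targets: concatenated calibrated segments.
synth_raw_day <- function(pid, pos, date, slot_starts_kept, u_kept, amp, gain,
                          slot_s, cfg, tremor = 0, fs = 100) {
  tl <- list(); axl <- list(); ayl <- list(); azl <- list()
  for (j in seq_along(slot_starts_kept)) {
    target <- amp * u_kept[j]^(1 / gain)
    if (cfg$noise_sd > 0)
      target <- max(0, target + amp * stats::rnorm(1, 0, cfg$noise_sd /
                                                     sqrt(slot_s / 5)))
    seg <- synthesize_raw_segment(target, slot_s, fs,
      tremor_amplitude = cfg$tremor_amplitude * tremor,
      tremor_freq_hz = cfg$tremor_freq_hz)
    tl[[j]] <- slot_starts_kept[j] + seg$t
    axl[[j]] <- seg$ax; ayl[[j]] <- seg$ay; azl[[j]] <- seg$az
  }
  raw_accel_recording(pid, pos, date, t = unlist(tl), ax = unlist(axl),
                      ay = unlist(ayl), az = unlist(azl), sampling_rate = fs)
}

#' Synthesize a raw tri-axial segment with a target mean ENMO
#'
#' Emits 100 Hz samples whose computed mean ENMO (gravity-subtracted norm,
#' low-pass, truncation) matches \code{target_enmo}: the dynamic component is
#' a band-limited two-tone oscillation on the x axis around a unit gravity
#' vector on z, with its scale calibrated by root finding on the emitted
#' waveform itself. An optional tremor component (4--6 Hz) is added on the
#' y axis after calibration, emulating a tremor-contaminated wrist.
#'
#' @param target_enmo Target mean ENMO in g (>= 0).
#' @param duration_s Segment duration in seconds.
#' @param fs Sampling rate (default 100 Hz).
#' @param base_freq_hz Range of the oscillation fundamental (default 1.5--4).
#' @param tremor_amplitude Tremor acceleration amplitude in g (default 0).
#' @param tremor_freq_hz Tremor frequency band (default 4--6 Hz).
#' @return Data frame \code{t} (seconds, from 0), \code{ax}, \code{ay},
#'   \code{az}.
#' @export
synthesize_raw_segment <- function(target_enmo, duration_s, fs = 100,
                                   base_freq_hz = c(1.5, 4),
                                   tremor_amplitude = 0,
                                   tremor_freq_hz = c(4, 6)) {
  if (target_enmo < 0) stop("synthesize_raw_segment: negative target",
                            call. = FALSE)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ax <- numeric(length(t)); ay <- numeric(length(t))
  if (target_enmo > 0) {
    f1 <- stats::runif(1, base_freq_hz[1], base_freq_hz[2])
    f2 <- stats::runif(1, base_freq_hz[1], base_freq_hz[2])
    wv <- sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) +
      0.6 * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi))
    gfun <- function(s) mean(sqrt(1 + (s * wv)^2) - 1) - target_enmo
    hi <- 2 * sqrt(2 * target_enmo) / max(stats::sd(wv), 1e-9) + 1
    while (gfun(hi) < 0) hi <- hi * 2
    s <- stats::uniroot(gfun, c(0, hi), tol = 1e-12)$root
    ax <- s * wv
  }
  if (tremor_amplitude > 0) {
    ftr <- stats::runif(1, tremor_freq_hz[1], tremor_freq_hz[2])
    # amplitude such that the added norm contribution ~ tremor_amplitude
    atr <- 2 * sqrt(max(tremor_amplitude, 0) / 2)
    ay <- atr * sin(2 * pi * ftr * t + stats::runif(1, 0, 2 * pi))
  }
  data.frame(t = t, ax = ax, ay = ay, az = rep(1, length(t)))
}

#' Write a synthetic bundle to disk
#'
#' Fast-path bundles write one 5-second epoch CSV per participant-day-sensor
#' (\code{enmo5s_<participant>_<date>_<position>.csv}); raw bundles write
#' \code{<participant>_<date>_<position>.csv} files with
#' \code{timestamp,ax,ay,az}. In both cases \code{diary.csv},
#' \code{compendium.csv}, \code{metadata.csv} and \code{ground_truth.json}
#' are emitted.
#'
#' @param bundle A \code{synth_bundle}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("write_bundle: cannot create %s", out_dir),
                call. = FALSE)
  if (!is.null(bundle$epochs)) {
    for (key in names(bundle$epochs)) {
      p <- strsplit(key, "|", fixed = TRUE)[[1]]
      ep <- bundle$epochs[[key]]
      df <- data.frame(epoch_start = format_tod(ep$epoch_start),
                       enmo_mean = ep$enmo_mean, n_samples = ep$n_samples)
      utils::write.csv(df, file.path(out_dir,
        sprintf("enmo5s_%s_%s_%s.csv", p[1], p[2], p[3])), row.names = FALSE)
    }
  }
  if (!is.null(bundle$raw)) {
    for (key in names(bundle$raw)) {
      p <- strsplit(key, "|", fixed = TRUE)[[1]]
      r <- bundle$raw[[key]]
      df <- data.frame(
        timestamp = paste0(r$date, "T", format_tod(floor(r$t)), ".",
                           sprintf("%03d", round((r$t %% 1) * 1000))),
        ax = r$ax, ay = r$ay, az = r$az)
      utils::write.csv(df, file.path(out_dir,
        sprintf("%s_%s_%s.csv", p[1], p[2], p[3])), row.names = FALSE)
    }
  }
  utils::write.csv(bundle$diary, file.path(out_dir, "diary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$compendium, file.path(out_dir, "compendium.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  gt <- bundle$ground_truth
  gt$schedule <- NULL                    # tabular part goes to CSV
  utils::write.csv(bundle$ground_truth$schedule,
                   file.path(out_dir, "ground_truth_schedule.csv"),
                   row.names = FALSE)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a fast-path epoch bundle directory
#'
#' Counterpart of [write_bundle()] for fast-path bundles: reads the
#' \code{enmo5s_*} epoch CSVs, diary, Compendium table and metadata back into
#' a bundle usable by [run_agreement()].
#'
#' @param dir Directory written by [write_bundle()].
#' @return A \code{synth_bundle}-shaped list (without ground truth).
#' @export
read_bundle <- function(dir) {
  files <- list.files(dir, pattern = "^enmo5s_.*\\.csv$", full.names = TRUE)
  if (!length(files))
    stop(sprintf("read_bundle: no enmo5s_*.csv files in %s", dir),
         call. = FALSE)
  epochs <- list()
  for (f in files) {
    p <- strsplit(sub("^enmo5s_", "", sub("\\.csv$", "", basename(f))),
                  "_", fixed = TRUE)[[1]]
    key <- paste(p[1], p[2], paste(p[-(1:2)], collapse = "_"), sep = "|")
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    ep <- data.frame(epoch_start = parse_tod(df$epoch_start),
                     enmo_mean = df$enmo_mean,
                     n_samples = as.integer(df$n_samples))
    class(ep) <- c("enmo_epochs", "data.frame")
    epochs[[key]] <- ep
  }
  diary <- utils::read.csv(file.path(dir, "diary.csv"),
                           stringsAsFactors = FALSE)
  comp_path <- file.path(dir, "compendium.csv")
  compendium <- read_compendium(comp_path)
  meta_path <- file.path(dir, "metadata.csv")
  metadata <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  structure(list(epochs = epochs, diary = diary, compendium = compendium,
                 metadata = metadata), class = "synth_bundle")
}
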