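#' Day- and participant-level inclusion rules
#'
#' Collects the thresholds used by [validate_day()] and [build_cohort()]:
#' a day is analyzable only if the recording starts at (or before) the window
#' start and ends at (or after) the window end, carries at least
#' \code{min_sensor_hours} of recorded sensor data, has at least one diary
#' entry, and has at least \code{min_simultaneous} 15-minute slots valid in
#' both the sensor and the diary arm; a participant is retained only with at
#' least \code{min_days} included days.
#'
#' @param min_simultaneous Minimum jointly valid slots per day (default 4).
#' @param min_days Minimum included days per participant (default 3).
#' @param min_sensor_hours Minimum recorded sensor time per day in hours
#'   (default 9).
#' @param hours_mode How sensor time is measured: \code{"sum"} (default,
#'   stricter: total covered time, gaps excluded) or \code{"span"}
#'   (wall-clock first-to-last sample).
#' @param window A [day_window].
#' @return A \code{qc_rules} list.
#' @export
qc_rules <- function(min_simultaneous = 4L, min_days = 3L,
                     min_sensor_hours = 9, hours_mode = c("sum", "span"),
                     window = day_window()) {
  hours_mode <- match.arg(hours_mode)
  stopifnot(min_simultaneous >= 0, min_days >= 1, min_sensor_hours >= 0)
  structure(list(min_simultaneous = as.integer(min_simultaneous),
                 min_days = as.integer(min_days),
                 min_sensor_hours = min_sensor_hours,
                 hours_mode = hours_mode, window = window),
            class = "qc_rules")
}

#' Validate one participant-day for one sensor position
#'
#' Computes the day-level inclusion flags and the joint-validity mask of the
#' two arms. The mask is symmetric: a slot is jointly valid iff it is valid
#' in both the ENMO and the MET series.
#'
#' @param enmo_day An \code{enmo_slots} data frame (one sensor, one day).
#' @param met_day A \code{met_slots} data frame (same participant-day).
#' @param sensor_span A [sensor_day_span()] list for the day's recording.
#' @param rules A [qc_rules].
#' @param participant,date,position Identifiers attached to the record; if
#'   both arms carry \code{participant}/\code{date} attributes they must
#'   agree, else an error is raised.
#' @return A \code{day_record} list with \code{flags} (sensor_hours_ok,
#'   window_ok, diary_present, simultaneity_ok), \code{n_simultaneous},
#'   \code{joint_valid} (logical per slot), \code{included}, and a
#'   human-readable \code{exclusion_reason} (NA when included).
#' @export
validate_day <- function(enmo_day, met_day, sensor_span, rules = qc_rules(),
                         participant, date, position) {
  for (arm in list(enmo_day, met_day)) {
    p <- attr(arm, "participant"); d <- attr(arm, "date")
    if (!is.null(p) && p != participant)
      stop(sprintf("validate_day: participant mismatch (%s vs %s)",
                   p, participant), call. = FALSE)
    if (!is.null(d) && d != date)
      stop(sprintf("validate_day: date mismatch (%s vs %s)", d, date),
           call. = FALSE)
  }
  if (nrow(enmo_day) != nrow(met_day))
    stop("validate_day: arms are on different slot grids", call. = FALSE)
  w <- rules$window
  hours <- if (rules$hours_mode == "sum") sensor_span$covered_hours
           else sensor_span$span_hours
  sensor_hours_ok <- isTRUE(hours >= rules$min_sensor_hours)
  window_ok <- isTRUE(!is.na(sensor_span$start) &&
                        sensor_span$start <= w$start &&
                        sensor_span$end >= w$end)
  n_entries <- attr(met_day, "n_entries")
  diary_present <- if (!is.null(n_entries)) n_entries > 0L else
    any(met_day$valid)
  joint_valid <- enmo_day$valid & met_day$valid
  n_sim <- sum(joint_valid)
  simultaneity_ok <- n_sim >= rules$min_simultaneous
  flags <- c(sensor_hours_ok = sensor_hours_ok, window_ok = window_ok,
             diary_present = diary_present, simultaneity_ok = simultaneity_ok)
  included <- all(flags)
  reason <- if (included) NA_character_ else
    paste(names(flags)[!flags], collapse = "+")
  structure(list(participant = participant, date = date, position = position,
                 flags = flags, n_simultaneous = n_sim,
                 joint_valid = joint_valid, included = included,
                 exclusion_reason = reason,
                 enmo = enmo_day$enmo_mean,
                 met_low = met_day$met_low, met_avg = met_day$met_avg,
                 met_high = met_day$met_high),
            class = "day_record")
}

#' Assemble the post-QC cohort panel for one sensor and one MET level
#'
#' Keeps included days of the requested sensor position, drops participants
#' with fewer than \code{rules$min_days} included days, and retains only
#' jointly valid slots, yielding aligned (ENMO, MET) epoch pairs.
#'
#' @param day_records List of \code{day_record}s (any positions mixed).
#' @param sensor_position Sensor to select.
#' @param met_level One of \code{"low"}, \code{"avg"}, \code{"high"}.
#' @param rules A [qc_rules].
#' @return A \code{cohort_panel} data frame with columns \code{participant,
#'   date, slot_index, enmo, met}; attributes \code{sensor_position},
#'   \code{met_level}, \code{n_participants}, \code{n_days},
#'   \code{epoch_counts} (named per participant), and \code{exclusions}
#'   (tally of day exclusion reasons for this sensor). Errors if the cohort
#'   is empty after filtering.
#' @export
build_cohort <- function(day_records, sensor_position,
                         met_level = c("low", "avg", "high"),
                         rules = qc_rules()) {
  met_level <- match.arg(met_level)
  sensor_position <- match.arg(sensor_position, sensor_positions())
  recs <- Filter(function(r) r$position == sensor_position, day_records)
  if (!length(recs))
    stop(sprintf("build_cohort: no day records for position %s",
                 sensor_position), call. = FALSE)
  excl <- table(unlist(lapply(recs, function(r)
    if (!r$included) r$exclusion_reason else NULL)))
  inc <- Filter(function(r) r$included, recs)
  days_per <- table(vapply(inc, `[[`, "", "participant"))
  keep_p <- names(days_per)[days_per >= rules$min_days]
  inc <- Filter(function(r) r$participant %in% keep_p, inc)
  if (!length(inc))
    stop(sprintf(
      "build_cohort: empty cohort for %s/%s after applying inclusion rules",
      sensor_position, met_level), call. = FALSE)
  met_col <- paste0("met_", met_level)
  rows <- lapply(inc, function(r) {
    j <- which(r$joint_valid)
    if (!length(j)) return(NULL)
    data.frame(participant = r$participant, date = r$date,
               slot_index = j - 1L, enmo = r$enmo[j], met = r[[met_col]][j],
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  if (is.null(panel) || !nrow(panel))
    stop("build_cohort: no jointly valid epochs in the included days",
         call. = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("cohort_panel", "data.frame")
  attr(panel, "sensor_position") <- sensor_position
  attr(panel, "met_level") <- met_level
  attr(panel, "n_participants") <- length(unique(panel$participant))
  attr(panel, "n_days") <- nrow(unique(panel[c("participant", "date")]))
  attr(panel, "epoch_counts") <- table(panel$participant)
  attr(panel, "exclusions") <- excl
  panel
}

#' Tabulate day-level QC outcomes
#'
#' @param day_records List of \code{day_record}s.
#' @return Data frame with one row per record: participant, date, position,
#'   the four flags, the simultaneous-slot count, inclusion and reason.
#' @export
qc_report <- function(day_records) {
  do.call(rbind, lapply(day_records, function(r) {
    data.frame(participant = r$participant, date = r$date,
               position = r$position,
               sensor_hours_ok = r$flags[["sensor_hours_ok"]],
               window_ok = r$flags[["window_ok"]],
               diary_present = r$flags[["diary_present"]],
               simultaneity_ok = r$flags[["simultaneity_ok"]],
               n_simultaneous = r$n_simultaneous,
               included = r$included,
               exclusion_reason = r$exclusion_reason,
               stringsAsFactors = FALSE)
  }))
}
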