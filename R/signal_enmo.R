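#' Raw tri-axial accelerometer recording
#'
#' Container for one sensor's acceleration samples for one participant-day.
#' Acceleration is expressed in gravitational units [g]; timestamps are
#' times of day in seconds since midnight (fractional seconds allowed) and
#' must be strictly increasing.
#'
#' @param participant_id Participant identifier.
#' @param sensor_position One of \code{"ankle"}, \code{"wrist"},
#'   \code{"lower_back"}.
#' @param date Calendar date (\code{Date} or \code{"YYYY-MM-DD"}).
#' @param t Numeric vector of times of day in seconds since midnight.
#' @param ax,ay,az Per-sample acceleration [g], same length as \code{t}.
#' @param sampling_rate Nominal sampling rate in Hz (default 100).
#' @return A \code{raw_accel_recording} object.
#' @export
raw_accel_recording <- function(participant_id, sensor_position, date,
                                t, ax, ay, az, sampling_rate = 100) {
  sensor_position <- match.arg(sensor_position, sensor_positions())
  n <- length(t)
  if (n == 0L) stop("raw_accel_recording: empty recording", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("raw_accel_recording: axis vectors must match timestamp length",
         call. = FALSE)
  if (any(diff(t) <= 0))
    stop("raw_accel_recording: timestamps must be strictly increasing",
         call. = FALSE)
  if (sampling_rate <= 0)
    stop("raw_accel_recording: sampling_rate must be positive", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         sensor_position = sensor_position,
         date = as.character(as.Date(date)),
         t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), sampling_rate = sampling_rate),
    class = "raw_accel_recording")
}

#' @export
print.raw_accel_recording <- function(x, ...) {
  cat(sprintf("<raw_accel_recording> %s %s %s: %d samples @ %g Hz, %s-%s\n",
              x$participant_id, x$date, x$sensor_position, length(x$t),
              x$sampling_rate, format_tod(min(x$t)), format_tod(max(x$t))))
  invisible(x)
}

#' @rdname raw_accel_recording
#' @export
sensor_positions <- function() c("ankle", "wrist", "lower_back")

#' Read a raw accelerometer CSV
#'
#' Expects a header \code{timestamp,ax,ay,az} with ISO-8601 timestamps and
#' acceleration in g. Participant, date and position are taken from the file
#' name pattern \code{<participant>_<date>_<position>.csv} unless given.
#'
#' @param path CSV file path.
#' @param participant_id,sensor_position,date Overrides for the metadata
#'   parsed from the file name.
#' @param sampling_rate Nominal sampling rate (default 100 Hz).
#' @return A [raw_accel_recording].
#' @export
read_raw_accel_csv <- function(path, participant_id = NULL,
                               sensor_position = NULL, date = NULL,
                               sampling_rate = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop(sprintf("raw accel CSV %s must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(participant_id)) participant_id <- parts[1]
  if (is.null(date)) date <- parts[2]
  if (is.null(sensor_position))
    sensor_position <- paste(parts[-(1:2)], collapse = "_")
  raw_accel_recording(participant_id, sensor_position, date,
                      t = parse_timestamp_tod(df$timestamp),
                      ax = df$ax, ay = df$ay, az = df$az,
                      sampling_rate = sampling_rate)
}

# ISO-8601 timestamp (or bare time) -> seconds since midnight, fractional.
parse_timestamp_tod <- function(ts) {
  ts <- as.character(ts)
  tod <- sub("^.*[T ]", "", ts)
  hh <- as.numeric(substr(tod, 1, 2))
  mm <- as.numeric(substr(tod, 4, 5))
  ss <- as.numeric(sub("^..:..:", "", tod))
  hh * 3600 + mm * 60 + ss
}

#' Compute ENMO from a raw recording
#'
#' ENMO (Euclidean Norm Minus One) isolates the dynamic component of
#' acceleration: the Euclidean norm of the three axes minus 1 g, low-pass
#' filtered (4th-order Butterworth, 20 Hz cutoff, zero-phase), with negative
#' values truncated to zero. With \code{mode = "post_norm"} (default) the
#' filter is applied to the (norm - 1) signal before truncation; with
#' \code{"per_axis"} each axis is filtered before the norm is taken;
#' \code{"bypass"} skips filtering.
#'
#' @param raw A [raw_accel_recording].
#' @param filter_cfg A [filter_config].
#' @return An \code{enmo_samples} data frame with columns \code{t} and
#'   \code{enmo} (nonnegative, in g), aligned to the input timestamps.
#'   Non-finite input samples are dropped; if more than 5\% are non-finite a
#'   warning is raised. The attribute \code{n_nonfinite} records the count.
#' @export
compute_enmo <- function(raw, filter_cfg = filter_config()) {
  stopifnot(inherits(raw, "raw_accel_recording"))
  fs <- raw$sampling_rate
  keep <- is.finite(raw$ax) & is.finite(raw$ay) & is.finite(raw$az) &
    is.finite(raw$t)
  n_bad <- sum(!keep)
  if (n_bad > 0.05 * length(keep))
    warning(sprintf("compute_enmo: %d of %d samples non-finite (> 5%%)",
                    n_bad, length(keep)))
  t <- raw$t[keep]
  ax <- raw$ax[keep]; ay <- raw$ay[keep]; az <- raw$az[keep]
  if (length(t) == 0L) stop("compute_enmo: no finite samples", call. = FALSE)
  if (filter_cfg$mode != "bypass" && fs <= 2 * filter_cfg$cutoff_hz)
    stop(sprintf(
      "Nyquist violation: sampling rate %g Hz must exceed twice the cutoff (%g Hz)",
      fs, filter_cfg$cutoff_hz), call. = FALSE)
  if (filter_cfg$mode == "per_axis") {
    ba <- butter_lowpass(filter_cfg$order, filter_cfg$cutoff_hz, fs)
    ax <- filtfilt(ba$b, ba$a, ax)
    ay <- filtfilt(ba$b, ba$a, ay)
    az <- filtfilt(ba$b, ba$a, az)
  }
  enmo <- sqrt(ax^2 + ay^2 + az^2) - 1
  if (filter_cfg$mode == "post_norm") {
    ba <- butter_lowpass(filter_cfg$order, filter_cfg$cutoff_hz, fs)
    enmo <- filtfilt(ba$b, ba$a, enmo)
  }
  enmo <- pmax(enmo, 0)
  out <- data.frame(t = t, enmo = enmo)
  class(out) <- c("enmo_samples", "data.frame")
  attr(out, "n_nonfinite") <- n_bad
  out
}

#' Aggregate per-sample ENMO into 5-second epochs
#'
#' Epochs are non-overlapping and anchored on the wall-clock grid (epoch
#' starts are multiples of \code{epoch_s} seconds since midnight); the epoch
#' mean is the arithmetic mean of the samples falling in
#' \code{[start, start + epoch_s)}. Epochs containing no samples are absent
#' from the output (gaps are not zero-filled).
#'
#' @param samples An \code{enmo_samples} data frame (columns \code{t},
#'   \code{enmo}).
#' @param epoch_s Epoch length in seconds (default 5).
#' @return An \code{enmo_epochs} data frame with \code{epoch_start} (seconds
#'   since midnight), \code{enmo_mean} and \code{n_samples}.
#' @export
aggregate_5s <- function(samples, epoch_s = 5) {
  if (NROW(samples) == 0L) {
    out <- data.frame(epoch_start = numeric(0), enmo_mean = numeric(0),
                      n_samples = integer(0))
    class(out) <- c("enmo_epochs", "data.frame")
    return(out)
  }
  if (any(diff(samples$t) <= 0))
    stop("aggregate_5s: timestamps must be strictly increasing", call. = FALSE)
  start <- floor(samples$t / epoch_s) * epoch_s
  sums <- rowsum(samples$enmo, start)
  cnts <- rowsum(rep(1L, length(start)), start)
  out <- data.frame(epoch_start = as.numeric(rownames(sums)),
                    enmo_mean = as.numeric(sums) / as.numeric(cnts),
                    n_samples = as.integer(cnts))
  rownames(out) <- NULL
  class(out) <- c("enmo_epochs", "data.frame")
  out
}

#' Aggregate 5-second epochs onto the 15-minute slot grid
#'
#' Each slot mean is the unweighted arithmetic mean of the 5-second epoch
#' means present in the slot; \code{coverage} is the fraction of expected
#' epochs present (180 per slot for 5-second epochs in a 15-minute slot) and
#' a slot is \code{valid} when coverage reaches \code{min_coverage}. All
#' slots of the window are always reported (36 for the default window), with
#' \code{enmo_mean = NA} where no epoch is present.
#'
#' @param epochs An \code{enmo_epochs} data frame.
#' @param window A [day_window] (default 09:00--18:00).
#' @param min_coverage Minimum epoch coverage for a slot to be valid
#'   (default 0.75).
#' @param epoch_s Epoch length in seconds (default 5).
#' @return An \code{enmo_slots} data frame with \code{slot_index} (0-based),
#'   \code{slot_start}, \code{enmo_mean}, \code{coverage}, \code{valid}.
#' @export
aggregate_slots <- function(epochs, window = day_window(), min_coverage = 0.75,
                            epoch_s = 5) {
  stopifnot(inherits(window, "day_window"))
  expected <- window$slot_s / epoch_s
  n <- window$n_slots
  mean_v <- rep(NA_real_, n)
  cnt <- rep(0L, n)
  if (NROW(epochs) > 0L) {
    idx <- slot_of(epochs$epoch_start, window)
    keep <- !is.na(idx)
    if (any(keep)) {
      grp <- idx[keep]
      sums <- rowsum(epochs$enmo_mean[keep], grp)
      cnts <- rowsum(rep(1L, sum(keep)), grp)
      at <- as.integer(rownames(sums)) + 1L
      mean_v[at] <- as.numeric(sums) / as.numeric(cnts)
      cnt[at] <- as.integer(cnts)
    }
  }
  coverage <- cnt / expected
  out <- data.frame(slot_index = seq(0L, n - 1L),
                    slot_start = slot_starts(window),
                    enmo_mean = mean_v,
                    coverage = coverage,
                    valid = coverage >= min_coverage & !is.na(mean_v))
  class(out) <- c("enmo_slots", "data.frame")
  out
}

#' Summarize the recorded span of a sensor day
#'
#' Used by the day-level QC rules: total covered time (sum of epoch lengths
#' present, gaps excluded), and the wall-clock start/end of the recording.
#'
#' @param epochs An \code{enmo_epochs} data frame for one participant-day.
#' @param epoch_s Epoch length in seconds.
#' @return List with \code{start}, \code{end} (seconds since midnight),
#'   \code{covered_hours} and \code{span_hours}.
#' @export
sensor_day_span <- function(epochs, epoch_s = 5) {
  if (NROW(epochs) == 0L)
    return(list(start = NA_real_, end = NA_real_, covered_hours = 0,
                span_hours = 0))
  s <- min(epochs$epoch_start)
  e <- max(epochs$epoch_start) + epoch_s
  list(start = s, end = e,
       covered_hours = NROW(epochs) * epoch_s / 3600,
       span_hours = (e - s) / 3600)
}
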