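#' Daytime analysis window
#'
#' Defines the daily analysis window on which 15-minute slots are laid out.
#' The default window 09:00--18:00 comprises 36 half-open slots
#' \code{[start, start + 15 min)}, the last one being 17:45--18:00.
#'
#' @param start,end Window bounds as \code{"HH:MM"} strings or seconds since
#'   midnight. The span must be a positive multiple of \code{slot_s}.
#' @param slot_s Slot length in seconds (default 900 = 15 minutes).
#' @return An object of class \code{day_window} with elements \code{start},
#'   \code{end} (seconds since midnight), \code{slot_s} and \code{n_slots}.
#' @examples
#' w <- day_window()
#' w$n_slots # 36
#' @export
day_window <- function(start = "09:00", end = "18:00", slot_s = 900) {
  start <- parse_tod(start)
  end <- parse_tod(end)
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop("day_window: end must be after start", call. = FALSE)
  span <- end - start
  if (span %% slot_s != 0)
    stop(sprintf(
      "day_window: window length (%ds) is not a multiple of the slot length (%ds)",
      span, slot_s), call. = FALSE)
  structure(
    list(start = start, end = end, slot_s = slot_s,
         n_slots = as.integer(span %/% slot_s)),
    class = "day_window")
}

#' @export
print.day_window <- function(x, ...) {
  cat(sprintf("<day_window> %s-%s, %d slots of %d s\n",
              format_tod(x$start), format_tod(x$end), x$n_slots, x$slot_s))
  invisible(x)
}

#' Parse a time of day to seconds since midnight
#'
#' Accepts numeric seconds (returned as-is), \code{"HH:MM"},
#' \code{"HH:MM:SS"}, or a full ISO-8601 timestamp (the date part is
#' ignored). Unparseable values yield NA.
#'
#' @param x Numeric or character vector.
#' @return Numeric seconds since midnight.
#' @export
parse_tod <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  x <- sub("^.*[T ]", "", x)               # strip date part if present
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2L || length(p) > 3L || anyNA(p)) return(NA_real_)
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

format_tod <- function(sec) {
  sec <- round(sec)
  sprintf("%02d:%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L)
}

# Slot index (0-based) of a time-of-day within a window; NA outside.
slot_of <- function(sec, window) {
  idx <- floor((sec - window$start) / window$slot_s)
  idx[sec < window$start | sec >= window$end] <- NA_real_
  as.integer(idx)
}

#' @rdname day_window
#' @param window A \code{day_window}.
#' @return For \code{slot_starts}, the slot start times in seconds since
#'   midnight.
#' @export
slot_starts <- function(window) {
  window$start + window$slot_s * seq(0L, window$n_slots - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
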