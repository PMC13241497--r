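#' Parse an activity diary table
#'
#' Validates tabular diary records (one row per reported activity). Rows are
#' rejected -- with a reason, never silently -- when the start/end times do
#' not parse, the duration is non-positive, or the intensity token is not one
#' of \code{mild}, \code{moderate}, \code{vigorous} (non-wear rows need no
#' intensity). Overlapping entries are permitted: participants may report
#' parallel activities (e.g. housekeeping while watching TV). Entries shorter
#' than \code{min_duration_s} are kept but flagged \code{sub_threshold},
#' mirroring the diary's 15-minute granularity.
#'
#' @param x A data frame (or CSV path) with columns
#'   \code{participant,date,start,end,activity,intensity} and optionally
#'   \code{non_wear} (logical or 0/1) and \code{comment}.
#' @param min_duration_s Minimum entry duration before flagging (default 900).
#' @return List with \code{entries} (validated data frame: \code{participant,
#'   date, start, end} in seconds since midnight, \code{activity, intensity,
#'   non_wear, sub_threshold, comment}) and \code{rejected} (offending rows
#'   with a \code{reason} column).
#' @export
parse_diary <- function(x, min_duration_s = 900) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("participant", "date", "start", "end", "activity", "intensity")
  if (!all(need %in% names(x)))
    stop(sprintf("parse_diary: missing columns: %s",
                 paste(setdiff(need, names(x)), collapse = ",")),
         call. = FALSE)
  if (is.null(x$non_wear)) x$non_wear <- FALSE
  if (is.null(x$comment)) x$comment <- ""
  non_wear <- as.logical(x$non_wear) %in% TRUE |
    x$non_wear %in% c(1, "1", "true", "TRUE", "yes")
  start <- parse_tod(x$start)
  end <- parse_tod(x$end)
  intensity <- tolower(trimws(as.character(x$intensity)))
  ok_int <- intensity %in% c("mild", "moderate", "vigorous") | non_wear
  reason <- rep(NA_character_, nrow(x))
  reason[is.na(start) | is.na(end)] <- "unparseable time"
  bad_dur <- !is.na(start) & !is.na(end) & end <= start
  reason[bad_dur] <- "negative duration"
  reason[is.na(reason) & !ok_int] <- "unknown intensity"
  keep <- is.na(reason)
  entries <- data.frame(
    participant = as.character(x$participant)[keep],
    date = as.character(x$date)[keep],
    start = start[keep], end = end[keep],
    activity = trimws(as.character(x$activity))[keep],
    intensity = intensity[keep],
    non_wear = non_wear[keep],
    sub_threshold = (end - start)[keep] < min_duration_s,
    comment = as.character(x$comment)[keep],
    stringsAsFactors = FALSE)
  rejected <- cbind(x[!keep, , drop = FALSE],
                    reason = reason[!keep])
  list(entries = entries, rejected = rejected)
}

#' Load a Compendium-style MET lookup table
#'
#' The table maps (activity label, self-reported intensity) pairs to a
#' Compendium code and MET value (multiples of resting metabolic rate). A row
#' with intensity \code{"any"} acts as a label-level default used when the
#' exact (label, intensity) pair is absent. The package bundles an editable
#' table of common household/leisure activities with approximate
#' Compendium-style values (\code{compendium_default.csv}); no bundled table
#' is claimed authoritative.
#'
#' @param path CSV path with columns \code{activity,intensity,code,met};
#'   \code{NULL} loads the bundled default table.
#' @return A \code{compendium_table} data frame.
#' @export
read_compendium <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compendium_default.csv",
                        package = "actidiary", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity", "intensity", "code", "met")
  if (!all(need %in% names(df)))
    stop("compendium CSV must have columns activity,intensity,code,met",
         call. = FALSE)
  df$activity <- tolower(trimws(df$activity))
  df$intensity <- tolower(trimws(df$intensity))
  if (any(df$met <= 0)) stop("compendium: met values must be > 0", call. = FALSE)
  key <- paste(df$activity, df$intensity, sep = "\r")
  if (anyDuplicated(key))
    stop("compendium: duplicate (activity, intensity) keys", call. = FALSE)
  class(df) <- c("compendium_table", "data.frame")
  df
}

#' Assign a MET value to a diary entry
#'
#' Exact (label, intensity) lookup in the Compendium table, falling back to a
#' label-level \code{"any"} row; entries that match neither are flagged
#' unmapped (and are excluded from the MET series by [diary_to_slots()]).
#'
#' @param activity Activity label.
#' @param intensity Intensity token (\code{mild}/\code{moderate}/
#'   \code{vigorous}).
#' @param table A \code{compendium_table}.
#' @return List with \code{met} (NA if unmapped), \code{code}, \code{mapped}.
#' @export
assign_met <- function(activity, intensity, table) {
  a <- tolower(trimws(activity)); i <- tolower(trimws(intensity))
  hit <- which(table$activity == a & table$intensity == i)
  if (!length(hit)) hit <- which(table$activity == a & table$intensity == "any")
  if (!length(hit))
    return(list(met = NA_real_, code = NA_character_, mapped = FALSE))
  list(met = table$met[hit[1]], code = as.character(table$code[hit[1]]),
       mapped = TRUE)
}

#' Map diary entries to low/average/high MET per 15-minute slot
#'
#' For each slot, the concurrent set is every mapped, non-non-wear activity
#' whose overlap with the slot reaches the membership threshold (default:
#' half the slot; \code{"any"} accepts any positive overlap). Then
#' \code{met_low} is the minimum MET over the concurrent set, \code{met_high}
#' the maximum, and \code{met_avg} the overlap-duration-weighted mean. A slot
#' covered by a single activity has all three levels equal. Slots reached by
#' a non-wear entry (at the same threshold), or by no activity, are invalid.
#'
#' @param entries Validated diary entries for one participant-day (see
#'   [parse_diary()]).
#' @param table A \code{compendium_table}.
#' @param window A [day_window].
#' @param overlap_rule \code{"half"} (default) or \code{"any"}.
#' @return A \code{met_slots} data frame with \code{slot_index, slot_start,
#'   met_low, met_avg, met_high, n_activities, valid}; attributes
#'   \code{n_unmapped} (entries without a Compendium match) and
#'   \code{n_entries}.
#' @export
diary_to_slots <- function(entries, table, window = day_window(),
                           overlap_rule = c("half", "any")) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(inherits(window, "day_window"))
  n <- window$n_slots
  ss <- slot_starts(window)
  se <- ss + window$slot_s
  thr <- if (overlap_rule == "half") window$slot_s / 2 else
    .Machine$double.eps
  met <- rep(NA_real_, nrow(entries))
  mapped <- rep(FALSE, nrow(entries))
  for (k in seq_len(NROW(entries))) {
    if (entries$non_wear[k]) next
    m <- assign_met(entries$activity[k], entries$intensity[k], table)
    met[k] <- m$met; mapped[k] <- m$mapped
  }
  n_unmapped <- sum(!mapped & !entries$non_wear)
  met_low <- met_avg <- met_high <- rep(NA_real_, n)
  n_act <- integer(n)
  non_wear_hit <- rep(FALSE, n)
  if (NROW(entries) > 0L) {
    # overlap of entry k with slot j, in seconds (n_entries x n_slots)
    ne <- NROW(entries)
    endm <- matrix(entries$end, ne, n)
    startm <- matrix(entries$start, ne, n)
    sem <- matrix(se, ne, n, byrow = TRUE)
    ssm <- matrix(ss, ne, n, byrow = TRUE)
    ov <- pmin(endm, sem) - pmax(startm, ssm)
    ov[ov < 0] <- 0
    reach <- ov >= thr
    nw <- entries$non_wear
    non_wear_hit <- apply(reach & nw, 2, any)
    use <- mapped & !nw
    for (j in seq_len(n)) {
      sel <- which(use & reach[, j])
      if (!length(sel)) next
      mets <- met[sel]
      w <- ov[sel, j]
      met_low[j] <- min(mets)
      met_high[j] <- max(mets)
      met_avg[j] <- sum(w * mets) / sum(w)
      n_act[j] <- length(sel)
    }
  }
  valid <- n_act > 0L & !non_wear_hit
  met_low[!valid] <- met_avg[!valid] <- met_high[!valid] <- NA_real_
  out <- data.frame(slot_index = seq(0L, n - 1L), slot_start = ss,
                    met_low = met_low, met_avg = met_avg, met_high = met_high,
                    n_activities = n_act, valid = valid)
  class(out) <- c("met_slots", "data.frame")
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_entries") <- NROW(entries)
  out
}
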