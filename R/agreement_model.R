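#' Fit a Min-Max normalization
#'
#' Stores the observed global minimum and maximum of a value pool so that
#' [apply_minmax()] maps min to 0 and max to 1. In the pipeline, ENMO is
#' normalized separately per sensor position and the three MET levels are
#' normalized jointly with one shared transformation, each over all subjects
#' and all daytime slots of the post-QC panel.
#'
#' @param values Numeric vector (NAs ignored); at least one finite value.
#' @return A \code{minmax_params} list with \code{min}, \code{max},
#'   \code{degenerate}.
#' @export
fit_minmax <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("fit_minmax: no finite values", call. = FALSE)
  mn <- min(v); mx <- max(v)
  deg <- mx <= mn
  if (deg) warning("fit_minmax: degenerate range (max == min); transform maps to 0")
  structure(list(min = mn, max = mx, degenerate = deg),
            class = "minmax_params")
}

#' @rdname fit_minmax
#' @param x Values to transform.
#' @param params A \code{minmax_params}.
#' @export
apply_minmax <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (params$degenerate) return(rep(0, length(x)) + 0 * x)
  (x - params$min) / (params$max - params$min)
}

#' Group-mean temporal profile
#'
#' Two-stage averaging per slot: each participant's values are first averaged
#' across their included days, then the group mean and SD are taken across
#' participant means (sample SD; NA with a single participant unless
#' \code{single_sd_zero}). A pooled single-stage alternative is available.
#'
#' @param panel A \code{cohort_panel} (columns \code{participant, slot_index}
#'   and the value column).
#' @param arm Which column to profile: \code{"enmo"} or \code{"met"}.
#' @param n_slots Number of slots in the grid (default 36).
#' @param stage \code{"two"} (default) or \code{"pooled"}.
#' @param single_sd_zero If TRUE, SD of a single participant is 0 instead of
#'   NA.
#' @return A \code{group_profile} data frame: \code{slot_index, mean, sd,
#'   n_participants}; slots observed in no participant have NA mean.
#' @export
group_profile <- function(panel, arm = c("enmo", "met"), n_slots = 36L,
                          stage = c("two", "pooled"),
                          single_sd_zero = FALSE) {
  arm <- match.arg(arm)
  stage <- match.arg(stage)
  v <- panel[[arm]]
  out <- data.frame(slot_index = seq(0L, n_slots - 1L), mean = NA_real_,
                    sd = NA_real_, n_participants = 0L)
  if (stage == "two") {
    pm <- stats::aggregate(v, by = list(participant = panel$participant,
                                        slot_index = panel$slot_index), FUN = mean)
    agg_m <- stats::aggregate(pm$x, by = list(slot_index = pm$slot_index), mean)
    agg_s <- stats::aggregate(pm$x, by = list(slot_index = pm$slot_index),
                              stats::sd)
    agg_n <- stats::aggregate(pm$x, by = list(slot_index = pm$slot_index), length)
  } else {
    agg_m <- stats::aggregate(v, by = list(slot_index = panel$slot_index), mean)
    agg_s <- stats::aggregate(v, by = list(slot_index = panel$slot_index),
                              stats::sd)
    agg_n <- stats::aggregate(v, by = list(slot_index = panel$slot_index), length)
  }
  at <- match(agg_m$slot_index, out$slot_index)
  out$mean[at] <- agg_m$x
  out$sd[at] <- agg_s$x
  out$n_participants[at] <- agg_n$x
  if (single_sd_zero) out$sd[out$n_participants == 1L] <- 0
  class(out) <- c("group_profile", "data.frame")
  out
}

#' Closed-form least-squares correction factor
#'
#' Analytic minimizer of the RMSE of the one-parameter model
#' \eqn{MET = \alpha \times ENMO}: \eqn{\alpha^* = \sum M_i E_i / \sum E_i^2}
#' over jointly present slots. Serves as the independent oracle for the
#' Nelder-Mead fit.
#'
#' @param e,m Numeric vectors of group-mean normalized ENMO and MET (NAs in
#'   either are dropped pairwise).
#' @return The exact least-squares \eqn{\alpha}.
#' @export
alpha_closed_form <- function(e, m) {
  ok <- is.finite(e) & is.finite(m)
  e <- e[ok]; m <- m[ok]
  if (!length(e) || all(e == 0))
    stop("alpha_closed_form: need at least one slot with nonzero ENMO",
         call. = FALSE)
  sum(m * e) / sum(e * e)
}

#' Nelder-Mead optimizer settings
#'
#' Tolerances are tighter than common library defaults so that the fitted
#' factor agrees with the closed-form least-squares solution to 1e-6 and a
#' zero-noise cohort closes to machine-level RMSE.
#'
#' @param xatol Absolute tolerance on the simplex width (default 1e-10).
#' @param fatol Absolute tolerance on the objective spread (default 1e-12).
#' @param maxiter Maximum iterations (default 1000).
#' @return An \code{optimizer_config} list.
#' @export
optimizer_config <- function(xatol = 1e-10, fatol = 1e-12, maxiter = 1000L) {
  structure(list(xatol = xatol, fatol = fatol, maxiter = as.integer(maxiter)),
            class = "optimizer_config")
}

#' One-dimensional Nelder-Mead simplex minimization
#'
#' Standard reflection/expansion/contraction/shrink simplex in one dimension
#' (two vertices), with the conventional coefficients (1, 2, 0.5, 0.5) and
#' the initial simplex \{x0, 1.05 x0\} (x0 + 0.00025 if x0 = 0). Terminates
#' when both the simplex width and the objective spread fall below the
#' tolerances.
#'
#' @param fn Objective function of one numeric argument.
#' @param x0 Starting point.
#' @param cfg An [optimizer_config].
#' @return List with \code{x}, \code{fval}, \code{converged}, \code{iter}.
#' @export
nelder_mead_1d <- function(fn, x0, cfg = optimizer_config()) {
  x <- c(x0, if (x0 != 0) 1.05 * x0 else 0.00025)
  f <- vapply(x, fn, numeric(1))
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$maxiter) {
    ord <- order(f)
    x <- x[ord]; f <- f[ord]
    if (abs(x[2] - x[1]) <= cfg$xatol && abs(f[2] - f[1]) <= cfg$fatol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    xr <- 2 * x[1] - x[2]              # reflection
    fr <- fn(xr)
    if (fr < f[1]) {
      xe <- 3 * x[1] - 2 * x[2]        # expansion
      fe <- fn(xe)
      if (fe < fr) { x[2] <- xe; f[2] <- fe } else { x[2] <- xr; f[2] <- fr }
    } else {
      # contraction (outside if reflection improved on the worst)
      if (fr < f[2]) { xc <- 1.5 * x[1] - 0.5 * x[2] } else {
        xc <- 0.5 * (x[1] + x[2])
      }
      fc <- fn(xc)
      if (fc < min(fr, f[2])) { x[2] <- xc; f[2] <- fc }
      else if (fr < f[2]) { x[2] <- xr; f[2] <- fr }
      else {                            # shrink toward the best vertex
        x[2] <- 0.5 * (x[1] + x[2])
        f[2] <- fn(x[2])
      }
    }
  }
  ord <- order(f)
  list(x = x[ord][1], fval = f[ord][1], converged = converged, iter = iter)
}

#' Fit the linear correction factor by Nelder-Mead
#'
#' Minimizes the RMSE between the group-mean normalized MET profile and
#' \eqn{\alpha \times} the group-mean normalized ENMO profile over jointly
#' present slots, initialized at the ratio of the two profile averages.
#'
#' @param group_enmo,group_met \code{group_profile} data frames (or plain
#'   numeric vectors of group means).
#' @param cfg An [optimizer_config].
#' @param sensor_position,met_level Labels carried into the result.
#' @return A \code{scaling_result} list: \code{alpha}, \code{fit_rmse},
#'   \code{init_alpha}, \code{converged}, \code{n_slots_used}, labels.
#'   Warns (and flags) on non-convergence.
#' @export
fit_alpha <- function(group_enmo, group_met, cfg = optimizer_config(),
                      sensor_position = NA_character_,
                      met_level = NA_character_) {
  e <- if (is.data.frame(group_enmo)) group_enmo$mean else group_enmo
  m <- if (is.data.frame(group_met)) group_met$mean else group_met
  ok <- is.finite(e) & is.finite(m)
  e <- e[ok]; m <- m[ok]
  if (length(e) < 2L)
    stop("fit_alpha: need at least two jointly present slots", call. = FALSE)
  if (all(e == 0))
    stop("fit_alpha: all group-mean ENMO values are zero", call. = FALSE)
  init <- mean(m) / mean(e)
  obj <- function(a) sqrt(mean((m - a * e)^2))
  res <- nelder_mead_1d(obj, init, cfg)
  if (!res$converged)
    warning("fit_alpha: Nelder-Mead did not converge within maxiter")
  structure(list(sensor_position = sensor_position, met_level = met_level,
                 alpha = res$x, fit_rmse = res$fval, init_alpha = init,
                 converged = res$converged, n_slots_used = length(e)),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> %s/%s: alpha = %.6f (init %.4f), RMSE = %.6f, %d slots%s\n",
              x$sensor_position, x$met_level, x$alpha, x$init_alpha,
              x$fit_rmse, x$n_slots_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Per-participant agreement RMSE
#'
#' For each participant, RMSE between the \eqn{\alpha}-corrected normalized
#' ENMO and the normalized MET over all their jointly valid epochs, pooling
#' included days (\code{per_day = TRUE} instead averages per-day RMSEs).
#' Corrected ENMO is clipped at 0 but not at 1.
#'
#' @param panel A normalized \code{cohort_panel}.
#' @param scaling A \code{scaling_result} for the same sensor and level.
#' @param per_day Pooling alternative (default FALSE = pool epochs).
#' @return Data frame \code{participant, sensor_position, met_level, rmse,
#'   n_epochs}. Participants without epochs are absent (with a warning
#'   upstream when that occurs at panel construction).
#' @export
subject_rmse <- function(panel, scaling, per_day = FALSE) {
  stopifnot(inherits(scaling, "scaling_result"))
  sp <- attr(panel, "sensor_position")
  lv <- attr(panel, "met_level")
  if (!is.na(scaling$sensor_position) && !is.null(sp) &&
      scaling$sensor_position != sp)
    stop("subject_rmse: scaling fitted for a different sensor position",
         call. = FALSE)
  resid2 <- (pmax(scaling$alpha * panel$enmo, 0) - panel$met)^2
  if (per_day) {
    day_rmse <- stats::aggregate(
      resid2, by = list(participant = panel$participant, date = panel$date),
      function(z) sqrt(mean(z)))
    agg <- stats::aggregate(day_rmse$x,
                            by = list(participant = day_rmse$participant), mean)
  } else {
    agg <- stats::aggregate(resid2, by = list(participant = panel$participant),
                            function(z) sqrt(mean(z)))
  }
  n <- stats::aggregate(resid2, by = list(participant = panel$participant),
                        length)
  data.frame(participant = agg$participant,
             sensor_position = sp %||% scaling$sensor_position,
             met_level = lv %||% scaling$met_level,
             rmse = agg$x,
             n_epochs = n$x[match(agg$participant, n$participant)],
             stringsAsFactors = FALSE)
}

#' Summarize per-participant RMSE distributions
#'
#' Median, minimum and maximum per sensor position and MET level (Table-1
#' layout). Even-count medians use the midpoint convention
#' (\code{stats::median}).
#'
#' @param agreements Data frame from [subject_rmse()] (rows of several
#'   sensor/level combinations may be concatenated).
#' @return Data frame \code{met_level, sensor_position, median, min, max, n}.
#' @export
summarize_rmse <- function(agreements) {
  sp <- factor(agreements$sensor_position, levels = sensor_positions())
  lv <- factor(agreements$met_level, levels = c("low", "avg", "high"))
  out <- do.call(rbind, lapply(split(agreements, list(lv, sp), drop = TRUE),
    function(g) data.frame(met_level = g$met_level[1],
                           sensor_position = g$sensor_position[1],
                           median = stats::median(g$rmse),
                           min = min(g$rmse), max = max(g$rmse),
                           n = nrow(g), stringsAsFactors = FALSE)))
  out <- out[order(factor(out$met_level, c("low", "avg", "high")),
                   factor(out$sensor_position, sensor_positions())), ]
  rownames(out) <- NULL
  out
}

#' Tremor subgroup label
#'
#' Subgroups follow the MDS-UPDRS Part III tremor items 3.15 + 3.16 + 3.17
#' summed on the most-affected side: \code{no_minimal} for a sum of 0 or 1,
#' \code{stronger} for a sum above 1.
#'
#' @param participant_id Identifier(s).
#' @param tremor_sum Integer sum(s) in 0--12.
#' @return Data frame \code{participant, tremor_sum, group}.
#' @export
tremor_label <- function(participant_id, tremor_sum) {
  stopifnot(all(tremor_sum >= 0 & tremor_sum <= 12))
  data.frame(participant = as.character(participant_id),
             tremor_sum = as.integer(tremor_sum),
             group = ifelse(tremor_sum <= 1, "no_minimal", "stronger"),
             stringsAsFactors = FALSE)
}

#' RMSE summaries stratified by tremor subgroup
#'
#' Applies [summarize_rmse()] within each tremor subgroup, for the wrist and
#' lower-back positions by default (the ankle can be enabled).
#'
#' @param labels Data frame from [tremor_label()]; every participant in
#'   \code{agreements} must be labeled.
#' @param agreements Data frame from [subject_rmse()].
#' @param positions Sensor positions to report.
#' @return Data frame with a leading \code{group} column.
#' @export
tremor_split <- function(labels, agreements,
                         positions = c("wrist", "lower_back")) {
  miss <- setdiff(unique(agreements$participant), labels$participant)
  if (length(miss))
    stop(sprintf("tremor_split: unlabeled participants: %s",
                 paste(miss, collapse = ",")), call. = FALSE)
  a <- agreements[agreements$sensor_position %in% positions, , drop = FALSE]
  a$group <- labels$group[match(a$participant, labels$participant)]
  out <- do.call(rbind, lapply(split(a, a$group), function(g) {
    s <- summarize_rmse(g)
    cbind(group = g$group[1], s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
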