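#' Low-pass filter configuration for ENMO computation
#'
#' @param order Filter order (default 4, per the standard ENMO pipeline).
#' @param cutoff_hz Low-pass cutoff frequency in Hz (default 20).
#' @param mode Where the filter is applied: \code{"post_norm"} filters the
#'   (norm - 1 g) signal before truncation (the literal reading of the
#'   pipeline description); \code{"per_axis"} filters each acceleration axis
#'   before the norm is taken (common in the field); \code{"bypass"} disables
#'   filtering, which makes `compute_enmo()` an exact
#'   norm-minus-one-then-truncate map.
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(order = 4L, cutoff_hz = 20,
                          mode = c("post_norm", "per_axis", "bypass")) {
  mode <- match.arg(mode)
  stopifnot(order >= 1L, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, mode = mode),
            class = "filter_config")
}

#' Butterworth low-pass filter design (bilinear transform)
#'
#' Digital Butterworth low-pass coefficients, matching
#' \code{scipy.signal.butter(order, w)} with normalized cutoff
#' \code{w = cutoff_hz / (fs/2)}.
#'
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param fs Sampling rate in Hz; must exceed twice the cutoff.
#' @return List with numerator \code{b} and denominator \code{a}.
#' @export
butter_lowpass <- function(order, cutoff_hz, fs) {
  if (fs <= 2 * cutoff_hz)
    stop(sprintf(
      "Nyquist violation: sampling rate %g Hz must exceed twice the cutoff (%g Hz)",
      fs, cutoff_hz), call. = FALSE)
  n <- as.integer(order)
  # analog prototype poles on the unit circle (Butterworth), pre-warped cutoff
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  p_analog <- complex(real = -sin(theta), imaginary = cos(theta))
  warped <- tan(pi * cutoff_hz / fs)   # = tan(w/2) with w in rad/sample
  p_analog <- p_analog * warped
  # bilinear transform z = (1 + s)/(1 - s) (fs normalized out by pre-warp)
  p_z <- (1 + p_analog) / (1 - p_analog)
  # n zeros at z = -1
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))
  a <- Re(poly_from_roots(p_z))
  # unit gain at DC
  gain <- sum(a) / sum(b)
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Direct-form IIR filter y = lfilter(b, a, x) with optional initial state zi
# (transposed direct form II, as in scipy). Implemented via stats::filter for
# speed: the MA part is a one-sided convolution, the AR part a recursion.
iir_filter <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  n <- max(nb, na)
  b <- c(b, rep(0, n - nb)) / a[1]
  a <- c(a, rep(0, n - na)) / a[1]
  nx <- length(x)
  if (nx == 0L) return(numeric(0))
  # MA part: u[t] = sum_j b[j] x[t-j+1], with zero history
  xp <- c(rep(0, n - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[n:(n + nx - 1)]
  # initial-state contribution enters the first n-1 outputs additively
  # through the recursion; fold zi into u via the state-space update below
  if (!is.null(zi)) {
    # transposed DF-II: y[t] = b1 x[t] + z1[t-1];
    # z_k[t] = b_{k+1} x[t] + z_{k+1}[t-1] - a_{k+1} y[t]
    # Run the first n-1 samples explicitly with state, then continue fast.
    z <- zi
    m <- length(z)              # n - 1
    y <- numeric(nx)
    head_len <- min(nx, m)
    for (t in seq_len(head_len)) {
      yt <- b[1] * x[t] + z[1]
      for (k in seq_len(m - 1)) z[k] <- b[k + 1] * x[t] + z[k + 1] - a[k + 1] * yt
      z[m] <- b[m + 1] * x[t] - a[m + 1] * yt
      y[t] <- yt
    }
    if (nx > m) {
      # remaining samples: standard recursion seeded with the computed head
      ar <- -a[-1]
      rest <- stats::filter(u[(m + 1):nx], ar, method = "recursive",
                            init = rev(y[seq_len(m)]))
      y[(m + 1):nx] <- as.numeric(rest)
    }
    return(y)
  }
  ar <- -a[-1]
  as.numeric(stats::filter(u, ar, method = "recursive"))
}

# Steady-state initial conditions of the transposed DF-II filter for a unit
# step input (scipy.signal.lfilter_zi): solve (I - A) zi = B companion form.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  m <- n - 1L
  IminusA <- diag(m) - companion_t(a)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

# transpose of the companion matrix of a (monic) polynomial
companion_t <- function(a) {
  m <- length(a) - 1L
  A <- matrix(0, m, m)
  A[1, ] <- -a[-1] / a[1]
  if (m > 1) A[cbind(2:m, 1:(m - 1))] <- 1
  t(A)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the output has no phase lag and
#' stays aligned with the input timestamps. Uses odd-reflection padding and
#' steady-state initial conditions, matching \code{scipy.signal.filtfilt}
#' defaults (\code{padtype = "odd"}, \code{padlen = 3 * max(len(a), len(b))}).
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal.
#' @param padlen Number of reflected samples prepended/appended.
#' @return Filtered signal, same length as \code{x}.
#' @export
filtfilt <- function(b, a, x, padlen = 3L * max(length(a), length(b))) {
  nx <- length(x)
  if (nx == 0L) return(numeric(0))
  padlen <- min(padlen, nx - 1L)
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[nx] - x[(nx - 1):(nx - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi = zi * y[length(y)]))
  if (padlen > 0L) y[(padlen + 1):(padlen + nx)] else y
}
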