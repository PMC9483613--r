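# Internal numerical helpers shared across the analysis modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and the command-line wrapper) can distinguish bad parameters from bad
#' data or protocol violations.
#' @noRd
sm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "spiralmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sm_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "spiralmap_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    sm_stop("invalid_parameter", "`%s` must be a single positive finite number", name)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    sm_stop("invalid_parameter", "`%s` must be a single non-negative finite number", name)
  invisible(x)
}

#' Single-pass IIR filter with zero initial conditions
#'
#' Direct-form transposed implementation via stats::filter: the FIR part as a
#' one-sided convolution, the AR part recursively. Coefficients as returned
#' by signal::butter (a[1] == 1 after normalisation).
#' @noRd
iir_filter <- function(x, b, a) {
  a <- as.numeric(a); b <- as.numeric(b)
  b <- b / a[1L]; a <- a / a[1L]
  n <- length(x)
  xp <- c(rep(0, length(b) - 1L), x)
  xb <- stats::filter(xp, b, method = "convolution", sides = 1L)
  xb <- as.numeric(xb)[length(b):(n + length(b) - 1L)]
  if (length(a) > 1L) {
    xb <- as.numeric(stats::filter(xb, -a[-1L], method = "recursive"))
  }
  xb
}

#' Zero-phase (forward-backward) low-pass filtering with odd-reflection padding
#'
#' The reflection padding keeps long-impulse-response filters (very low
#' normalised cutoffs) from leaking edge transients into the signal, which
#' matters when the filtered profile is thresholded near the path ends.
#' @noRd
zero_phase_filter <- function(x, b, a, pad = NULL) {
  n <- length(x)
  if (n < 4L) return(x)
  if (is.null(pad)) pad <- n - 1L
  pad <- min(pad, n - 1L)
  # filter about the mean: for a unit-DC-gain low-pass this is exact and
  # keeps the zero-state transient proportional to the AC excursion rather
  # than to a large baseline (a constant input comes back bit-exact)
  mu <- mean(x)
  x <- x - mu
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter(xp, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(pad + 1L):(pad + n)] + mu
}

#' Low-pass Butterworth, zero phase, cutoff as a fraction of Nyquist
#' @noRd
butter_lowpass_zerophase <- function(x, cutoff, order = 3L, pad = NULL) {
  if (cutoff <= 0 || cutoff >= 1)
    sm_stop("invalid_parameter", "normalised cutoff must lie in (0, 1), got %g", cutoff)
  bf <- signal::butter(order, cutoff, type = "low")
  if (is.null(pad)) pad <- min(length(x) - 1L, ceiling(3 / cutoff))
  zero_phase_filter(x, bf$b, bf$a, pad = pad)
}

#' Robust noise floor of a uniformly sampled trace
#'
#' Median absolute first difference, scaled to the standard deviation of the
#' underlying white noise (|N(0,1) - N(0,1)| has median ~0.954 * sqrt(2)).
#' @noRd
noise_floor <- function(v) {
  d <- diff(v)
  median(abs(d - median(d))) / (0.6745 * sqrt(2))
}

#' Sub-sample level crossings by linear interpolation
#'
#' Returns the interpolated x of every crossing of `level` in the requested
#' direction ("up" = from below to >= level).
#' @noRd
level_crossings <- function(x, v, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  below <- v < level
  idx <- if (direction == "up") which(below[-length(v)] & !below[-1L])
         else which(!below[-length(v)] & below[-1L])
  if (length(idx) == 0L) return(numeric(0))
  frac <- (level - v[idx]) / (v[idx + 1L] - v[idx])
  x[idx] + frac * (x[idx + 1L] - x[idx])
}

#' Moving median smoother (odd window), edges handled by shrinking the window
#' @noRd
moving_median <- function(v, k = 5L) {
  if (k <= 1L) return(v)
  n <- length(v)
  h <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- median(v[lo:hi])
  }
  out
}

#' Box (boxcar) mean filter of a matrix with a k x k window
#'
#' Uses an integral image; edges use the partial (truncated) window, so a
#' constant matrix is reproduced exactly.
#' @noRd
box_mean <- function(m, k = 7L) {
  if (k <= 1L) return(m)
  h <- k %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(0L, seq_len(nr) - h - 1L); r2 <- pmin(nr, seq_len(nr) + h)
  c1 <- pmax(0L, seq_len(nc) - h - 1L); c2 <- pmin(nc, seq_len(nc) + h)
  # sums over [r1+1, r2] x [c1+1, c2] via inclusion-exclusion on the integral image
  S <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1 + 1L, c2 + 1L, drop = FALSE] -
       ii[r2 + 1L, c1 + 1L, drop = FALSE] + ii[r1 + 1L, c1 + 1L, drop = FALSE]
  counts <- outer(r2 - r1, c2 - c1)
  S / counts
}

#' Standard error of the mean (NA for a single observation)
#' @noRd
sem <- function(x) {
  n <- sum(is.finite(x))
  if (n < 2L) return(NA_real_)
  sd(x[is.finite(x)]) / sqrt(n)
}
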