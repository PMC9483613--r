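# Action-potential event detection on uniformly sampled traces.
#
# All downstream measurements (APD at a repolarisation level, peak times,
# upstroke velocity) share this detector: action potentials are located by
# upstroke crossings of 50% of the trace amplitude, each event owning the
# diastolic interval that precedes it.

#' Detect action potentials in a trace
#'
#' @param time_ms Sample times, ms (uniform).
#' @param v Trace values.
#' @param min_separation_ms Minimal distance between distinct upstrokes, ms.
#' @param min_snr Minimal amplitude over the noise floor; below it the trace
#'   is declared signal-free.
#' @param min_amplitude Optional absolute amplitude floor. Callers that
#'   smooth before detection should pass `min_snr` times the noise floor of
#'   the raw trace: smoothing correlates the noise, the in-trace floor
#'   estimate then collapses, and the quantile amplitude of pure noise
#'   (~4 sigma regardless of its size) would pass the relative gate.
#' @return A data.frame with one row per action potential: sample indices
#'   `start_idx` (diastole start), `onset_idx` (upstroke), `peak_idx`,
#'   `end_idx`, and values `base` (preceding diastolic baseline), `peak`.
#'   Errors with class `no_signal` when no supra-noise AP exists.
#' @export
detect_aps <- function(time_ms, v, min_separation_ms = 100, min_snr = 3,
                       min_amplitude = NULL) {
  stopifnot(length(time_ms) == length(v))
  b0 <- quantile(v, 0.05, names = FALSE)
  # robust peak reference: a filter edge transient of a few samples must not
  # inflate the detection threshold above the true action-potential peaks
  amp <- quantile(v, 0.995, names = FALSE) - b0
  nf <- noise_floor(v)
  if (!is.finite(amp) || amp <= 0 || amp < min_snr * max(nf, .Machine$double.eps))
    sm_stop("no_signal", "no action potential above the noise floor (amplitude %.3g, noise %.3g)",
            amp, nf)
  if (!is.null(min_amplitude) && amp < min_amplitude)
    sm_stop("no_signal", "amplitude %.3g below the raw-trace noise gate %.3g",
            amp, min_amplitude)
  thr <- b0 + 0.5 * amp
  above <- v >= thr
  # hysteresis: an upstroke only re-arms once the trace has fallen below 25%
  # of the amplitude, so noise chatter where a slow repolarisation grazes
  # the 50% threshold cannot spawn spurious events
  state <- ifelse(above, 1L, ifelse(v <= b0 + 0.25 * amp, -1L, 0L))
  nz <- which(state != 0L)
  sv <- state[nz]
  prev <- c(-1L, sv[-length(sv)])
  onsets <- nz[sv == 1L & prev == -1L]
  if (length(onsets) == 0L)
    sm_stop("no_signal", "no upstroke crossing found")
  dt <- time_ms[2L] - time_ms[1L]
  min_sep <- max(1L, round(min_separation_ms / dt))
  keep <- c(TRUE, diff(onsets) >= min_sep)
  onsets <- onsets[keep]
  n <- length(onsets)
  ends <- c(onsets[-1L] - 1L, length(v))
  starts <- c(1L, onsets[-n])
  out <- data.frame(start_idx = starts, onset_idx = onsets, end_idx = ends,
                    peak_idx = NA_integer_, base = NA_real_, peak = NA_real_)
  for (i in seq_len(n)) {
    seg <- onsets[i]:ends[i]
    out$peak_idx[i] <- seg[which.max(v[seg])]
    dia <- starts[i]:max(starts[i], onsets[i] - 1L)
    out$base[i] <- quantile(v[dia], 0.05, names = FALSE)
    out$peak[i] <- v[out$peak_idx[i]]
  }
  # drop events truncated by the recording boundaries: an AP already above
  # threshold at the first sample, or one whose repolarisation has not come
  # back within 20% of its amplitude by the last sample
  drop <- logical(n)
  if (out$onset_idx[1L] <= 1L) drop[1L] <- TRUE
  if (out$end_idx[n] == length(v) &&
      v[length(v)] > out$base[n] + 0.2 * (out$peak[n] - out$base[n]))
    drop[n] <- TRUE
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0L)
    sm_stop("no_signal", "only boundary-truncated action potentials found")
  out
}

#' Duration of one action potential at a repolarisation percentage
#'
#' Time between the upstroke and repolarisation crossings of the level
#' `base + (1 - p/100) * amplitude`, both sub-sample interpolated. Returns
#' NA when either crossing is missing (e.g. the AP is truncated by the end
#' of the recording).
#' @noRd
ap_duration <- function(time_ms, v, ap, p) {
  amp <- ap$peak - ap$base
  level <- ap$base + (1 - p / 100) * amp
  pre <- ap$start_idx:ap$peak_idx
  post <- ap$peak_idx:ap$end_idx
  up <- level_crossings(time_ms[pre], v[pre], level, "up")
  dn <- level_crossings(time_ms[post], v[post], level, "down")
  if (length(up) == 0L || length(dn) == 0L) return(NA_real_)
  dn[1L] - up[length(up)]
}

#' Sub-sample peak time of one action potential
#'
#' Midpoint of the sub-sample interpolated half-amplitude crossings around
#' the peak. The estimator is shape-consistent: applied to two time-shifted
#' copies of the same waveform it returns times differing by exactly the
#' shift, so peak-time differences between recording sites are sub-sample
#' accurate even for flat-topped optical action potentials (for which the
#' discrete argmax carries up to one sample of phase-locked quantisation
#' bias that does not average out across a paced train).
#' @noRd
ap_peak_time <- function(time_ms, v, ap, frac = 0.5) {
  level <- ap$base + frac * (ap$peak - ap$base)
  pre <- ap$start_idx:ap$peak_idx
  post <- ap$peak_idx:ap$end_idx
  up <- level_crossings(time_ms[pre], v[pre], level, "up")
  dn <- level_crossings(time_ms[post], v[post], level, "down")
  if (length(up) == 0L || length(dn) == 0L) return(time_ms[ap$peak_idx])
  (up[length(up)] + dn[1L]) / 2
}

#' Remove first-order fluorescence drift from a trace
#'
#' Fits a straight line to the diastolic samples (those below the median of
#' the residual from an initial whole-trace fit, so the action potentials do
#' not bias the slope) and subtracts it, restoring the original mean level.
#' Removes photobleaching drift, which on a ~2% dF/F voltage-dye signal is
#' of the same order as the signal itself.
#'
#' @param v Trace values.
#' @return Detrended trace (same mean).
#' @export
detrend_trace <- function(v) {
  trend <- fit_diastolic_trend(v)
  v - trend + mean(trend)
}

#' First-order trend fitted to the diastolic samples of a trace
#' @noRd
fit_diastolic_trend <- function(v, dia_frac = 0.2) {
  # anchor the line to the lowest-residual quintile so it tracks diastole
  # even when a long action potential fills most of the window
  t <- seq_along(v)
  fit1 <- lm.fit(cbind(1, t), v)
  dia <- fit1$residuals <= quantile(fit1$residuals, dia_frac, names = FALSE)
  fit2 <- lm.fit(cbind(1, t[dia]), v[dia])
  fit2$coefficients[1L] + fit2$coefficients[2L] * t
}

#' Default line-scan smoother: detrend, moving median, zero-phase low-pass
#'
#' Stands in for the (unreproducible) chain-smoothing of the original
#' acquisition software: first-order drift removal ([detrend_trace()]), a
#' 5-sample moving median for impulsive noise, and a zero-phase 3rd-order
#' Butterworth low-pass at `lowpass_hz` for the rest. The cutoff is clipped
#' below Nyquist with a warning if needed.
#'
#' @param v Trace values.
#' @param frame_rate Sampling rate, Hz.
#' @param median_window Moving-median window, samples.
#' @param lowpass_hz Low-pass cutoff, Hz (NULL disables).
#' @param detrend Remove first-order drift first.
#' @return Smoothed trace.
#' @export
smooth_trace <- function(v, frame_rate, median_window = 5L, lowpass_hz = 40,
                         detrend = TRUE) {
  out <- if (detrend) detrend_trace(v) else v
  out <- moving_median(out, median_window)
  if (!is.null(lowpass_hz) && lowpass_hz > 0) {
    w <- 2 * lowpass_hz / frame_rate
    if (w >= 1) {
      sm_warn("cutoff_clipped", "low-pass cutoff %g Hz at or above Nyquist (%g Hz); clipped",
              lowpass_hz, frame_rate / 2)
      w <- 0.9
    }
    out <- butter_lowpass_zerophase(out, w)
  }
  out
}
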