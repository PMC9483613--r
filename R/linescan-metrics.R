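# Line-scan endpoints: APD80 from a regional fluorescence trace, travel time
# and conduction velocity between two regions, and the calculated
# wavelength CV x APD (or CV x ERP).

#' APD at 80% repolarisation from a line-scan fluorescence trace
#'
#' Per action potential the amplitude is the peak minus the preceding
#' diastolic baseline, and the duration is measured between the sub-sample
#' interpolated upstroke and repolarisation crossings of 20% of the
#' amplitude above baseline (i.e. 80% repolarisation). The trace is smoothed
#' first ([smooth_trace()], pluggable); all complete APs are averaged.
#'
#' @param trace Numeric vector, or a data.frame with a `value` column.
#' @param frame_rate Sampling rate, Hz.
#' @param p Repolarisation percentage (default 80).
#' @param smoother Function `(v, frame_rate) -> v` applied before
#'   measurement; `NULL` disables smoothing.
#' @param min_separation_ms Minimal AP separation for event detection.
#' @return Mean APD, ms, with attribute `per_ap` (the individual durations).
#'   Errors with class `no_signal` if no supra-noise AP exists.
#' @export
linescan_apd <- function(trace, frame_rate, p = 80, smoother = smooth_trace,
                         min_separation_ms = 100) {
  v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  check_positive(frame_rate, "frame_rate")
  raw_gate <- 3 * noise_floor(v)
  if (!is.null(smoother)) v <- smoother(v, frame_rate)
  tt <- (seq_along(v) - 1L) / frame_rate * 1000
  aps <- detect_aps(tt, v, min_separation_ms = min_separation_ms,
                    min_amplitude = raw_gate)
  durs <- vapply(seq_len(nrow(aps)), function(i) ap_duration(tt, v, aps[i, ], p),
                 numeric(1))
  durs <- durs[is.finite(durs)]
  if (length(durs) == 0L)
    sm_stop("no_signal", "no complete action potential to measure")
  out <- mean(durs)
  attr(out, "per_ap") <- durs
  out
}

#' @rdname linescan_apd
#' @export
linescan_apd80 <- function(trace, frame_rate, ...) {
  linescan_apd(trace, frame_rate, p = 80, ...)
}

#' Travel time and conduction velocity between two line-scan regions
#'
#' Travel time is the mean, over paired action potentials, of the difference
#' between peak times at the distal and proximal regions; CV is the arc
#' separation divided by the travel time. Peaks are paired in order after
#' trimming an AP that is missing at one end of either recording; any other
#' count mismatch is a pairing error.
#'
#' @param trace_a,trace_b Proximal / distal traces (vectors or data.frames
#'   with `value`), simultaneously recorded at the same rate.
#' @param arc_separation_cm Arc distance between the region centres, cm.
#' @param frame_rate Sampling rate, Hz.
#' @param smoother As in [linescan_apd()].
#' @param min_separation_ms Minimal AP separation.
#' @return A list: `travel_time_ms`, `cv_cm_s`, `n_pairs`,
#'   `direction_flipped` (TRUE when the distal region led and the absolute
#'   value was used, with a warning).
#' @export
travel_time_and_cv <- function(trace_a, trace_b, arc_separation_cm,
                               frame_rate, smoother = smooth_trace,
                               min_separation_ms = 100) {
  check_positive(arc_separation_cm, "arc_separation_cm")
  check_positive(frame_rate, "frame_rate")
  get_peaks <- function(trace) {
    v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
    raw_gate <- 3 * noise_floor(v)
    if (!is.null(smoother)) v <- smoother(v, frame_rate)
    tt <- (seq_along(v) - 1L) / frame_rate * 1000
    aps <- detect_aps(tt, v, min_separation_ms = min_separation_ms,
                      min_amplitude = raw_gate)
    vapply(seq_len(nrow(aps)), function(i) ap_peak_time(tt, v, aps[i, ]), numeric(1))
  }
  pa <- get_peaks(trace_a)
  pb <- get_peaks(trace_b)
  if (abs(length(pa) - length(pb)) > 2L)
    sm_stop("pairing_error", "cannot pair %d and %d action potentials",
            length(pa), length(pb))
  # Both sites see the same paced train, but either recording may have lost
  # a boundary beat, so beat correspondence is ambiguous up to a shift of
  # the pacing cycle. The proximal site (trace_a) leads, so the physical
  # alignment is the one with the smallest positive mean delay; a negative
  # delay is accepted (with a warning) only when no alignment leads forward.
  cand <- list()
  for (s in -2:2) {
    ib <- seq_along(pb)
    ia <- ib + s
    keep <- ia >= 1L & ia <= length(pa)
    if (sum(keep) < 2L) next
    cand[[length(cand) + 1L]] <- pb[ib[keep]] - pa[ia[keep]]
  }
  if (length(cand) == 0L)
    sm_stop("pairing_error", "too few action potentials to pair")
  means <- vapply(cand, mean, numeric(1))
  # effectively identical traces: some alignment has zero delay
  if (any(abs(means) < 0.5 * 1000 / frame_rate))
    sm_stop("degenerate_signal", "zero travel time: conduction velocity undefined")
  pos <- which(means > 0)
  best <- if (length(pos) > 0L) pos[which.min(means[pos])] else which.min(abs(means))
  dt <- cand[[best]]
  travel <- mean(dt)
  flipped <- FALSE
  if (travel < 0) {
    sm_warn("direction_warning",
            "distal region leads the proximal one; using |travel time|")
    travel <- abs(travel)
    flipped <- TRUE
  }
  list(travel_time_ms = travel,
       cv_cm_s = arc_separation_cm / (travel / 1000),
       n_pairs = length(dt),
       direction_flipped = flipped)
}

#' Calculated conduction wavelength
#'
#' WL = CV x duration, the spatial extent of tissue depolarised by one wave.
#' The duration may be an APD80 (surrogate) or an ERP.
#'
#' @param cv_cm_s Conduction velocity, cm/s (> 0).
#' @param duration_ms APD or ERP, ms (> 0).
#' @return Wavelength, cm.
#' @export
#' @examples
#' wavelength_calculated(8, 300)   # 2.4 cm
#' wavelength_calculated(54, 224)  # 12.096 cm
wavelength_calculated <- function(cv_cm_s, duration_ms) {
  check_positive(cv_cm_s, "cv_cm_s")
  check_positive(duration_ms, "duration_ms")
  cv_cm_s * duration_ms / 1000
}

#' Regress directly measured wavelength on calculated wavelength
#'
#' Ordinary least squares (with intercept) of measured on calculated WL over
#' a set of spiral endpoint records, plus the Pearson correlation.
#'
#' @param records A data.frame with columns `wl_measured` and
#'   `wl_calculated`; rows with a missing measured WL are dropped.
#' @return A list: `slope`, `intercept`, `r`, `n`.
#' @export
wl_validation <- function(records) {
  stopifnot(all(c("wl_measured", "wl_calculated") %in% names(records)))
  d <- records[is.finite(records$wl_measured) & is.finite(records$wl_calculated), ]
  if (nrow(d) < 3L)
    sm_stop("invalid_input", "need at least 3 records with both wavelengths, got %d", nrow(d))
  if (sd(d$wl_calculated) < 1e-12)
    sm_stop("singular_fit", "calculated wavelengths are all equal; regression is singular")
  fit <- lm(wl_measured ~ wl_calculated, data = d)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r = cor(d$wl_calculated, d$wl_measured),
       n = nrow(d))
}
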