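# Patch-clamp action-potential feature extraction and the rule-based
# nodal / atrial / ventricular classifier.
#
# Two rule sets are provided because the published classification procedure
# and its figure caption differ slightly (working-myocyte MDP bound of -55
# vs -60 mV, OR-joined vs jointly-listed duration criteria):
#   * "text" (default): nodal if APA < 100 mV and MDP > -50 mV and
#     dV/dt_max < 5 V/s; cells with MDP < -55 mV and dV/dt_max > 5 V/s are
#     ventricular if (APD90 > 400 ms or APD90/APD50 < 1.2) and atrial if
#     (APD90 < 300 ms or APD90/APD50 > 1.2); a cell satisfying both
#     disjunctions (e.g. APD90 = 350 ms with ratio 1.3) is never silently
#     tie-broken - it is unclassified with the conflict recorded.
#   * "caption": all criteria joint; atrial: MDP < -60, APA > 100,
#     dV/dt_max > 5, APD90 < 300, ratio > 1.2; ventricular: MDP < -60,
#     APA > 100, dV/dt_max > 5, APD90 > 400, ratio < 1.2; nodal as above.
# Either way the MDP gap between the nodal and working-myocyte rules leaves
# a band of unclassifiable cells; this is preserved, not patched.

#' Extract action-potential features from a patch-clamp trace
#'
#' Per action potential: MDP is the minimum of the preceding diastolic
#' interval; APA the peak minus MDP; dV/dt_max the maximal first difference
#' over the sampling step during the upstroke (mV/ms, numerically V/s);
#' APD50 and APD90 the sub-sample interpolated durations at 50% and 90%
#' repolarisation from peak toward MDP. Multiple action potentials are
#' averaged.
#'
#' @param trace A data.frame with `time_ms` and `voltage_mv`, or a numeric
#'   vector with `sample_rate` given.
#' @param sample_rate Sampling rate, Hz (>= 1 kHz); inferred from `time_ms`
#'   when a data.frame is given.
#' @param min_separation_ms Minimal AP separation.
#' @param median_window Moving-median prefilter width, samples; keeps
#'   single-sample noise extremes out of the MDP and peak statistics while
#'   preserving monotone upstroke slopes.
#' @return An object of class `ap_features`: a one-row tibble with `mdp`,
#'   `apa`, `dvdt_max`, `apd50`, `apd90`, `apd_ratio`, `n_aps`.
#'   Errors with class `no_signal` for a flat trace.
#' @export
extract_features <- function(trace, sample_rate = NULL, min_separation_ms = 100,
                             median_window = 5L) {
  if (is.data.frame(trace)) {
    tt <- trace$time_ms
    v <- trace$voltage_mv
    sample_rate <- 1000 / median(diff(tt))
  } else {
    if (is.null(sample_rate))
      sm_stop("invalid_parameter", "sample_rate required for a bare numeric trace")
    v <- as.numeric(trace)
    tt <- (seq_along(v) - 1L) / sample_rate * 1000
  }
  if (sample_rate < 1000)
    sm_stop("invalid_parameter", "sampling rate %.0f Hz below the 1 kHz minimum", sample_rate)
  v <- moving_median(v, median_window)
  aps <- detect_aps(tt, v, min_separation_ms = min_separation_ms)
  dt <- tt[2L] - tt[1L]
  # derivative as a sliding least-squares slope over ~1 ms: the raw first
  # difference takes its maximum over noise spikes, which on a shallow
  # nodal upstroke can triple the apparent dV/dt_max
  h <- max(2L, round(1 / dt))
  iw <- -h:h
  slope_kernel <- iw / (sum(iw^2) * dt)
  dv <- stats::filter(v, rev(slope_kernel), method = "convolution", sides = 2L)
  rows <- lapply(seq_len(nrow(aps)), function(i) {
    ap <- aps[i, ]
    dia <- ap$start_idx:max(ap$start_idx, ap$onset_idx - 1L)
    mdp <- min(v[dia])
    apa <- ap$peak - mdp
    up <- max(ap$start_idx, ap$onset_idx - ceiling(50 / dt)):ap$peak_idx
    dvdt <- max(dv[up], na.rm = TRUE)
    a50 <- ap_duration(tt, v, ap, 50)
    a90 <- ap_duration(tt, v, ap, 90)
    data.frame(mdp = mdp, apa = apa, dvdt_max = dvdt, apd50 = a50, apd90 = a90)
  })
  feat <- do.call(rbind, rows)
  feat <- feat[stats::complete.cases(feat), , drop = FALSE]
  if (nrow(feat) == 0L)
    sm_stop("no_signal", "no complete action potential to measure")
  out <- tibble::tibble(mdp = mean(feat$mdp), apa = mean(feat$apa),
                        dvdt_max = mean(feat$dvdt_max),
                        apd50 = mean(feat$apd50), apd90 = mean(feat$apd90),
                        apd_ratio = mean(feat$apd90) / mean(feat$apd50),
                        n_aps = nrow(feat))
  class(out) <- c("ap_features", class(out))
  out
}

#' Build an `ap_features` row from known values
#'
#' Convenience constructor for classifying tabulated features.
#' @param mdp,apa,dvdt_max,apd90 Feature values (mV, mV, V/s, ms).
#' @param apd_ratio APD90/APD50.
#' @param apd50 APD50, ms; derived from `apd90 / apd_ratio` when missing.
#' @return An `ap_features` tibble row.
#' @export
ap_features <- function(mdp, apa, dvdt_max, apd90, apd_ratio, apd50 = apd90 / apd_ratio) {
  out <- tibble::tibble(mdp = mdp, apa = apa, dvdt_max = dvdt_max,
                        apd50 = apd50, apd90 = apd90,
                        apd_ratio = apd_ratio, n_aps = NA_integer_)
  class(out) <- c("ap_features", class(out))
  out
}

#' Classify an action potential as nodal, atrial, ventricular, or unclassified
#'
#' Applies one of the two rule sets (see the module notes above); the
#' returned `rule_trace` lists every criterion evaluated and why the label
#' (or the refusal to label) followed. Deterministic and total: every input
#' receives exactly one label.
#'
#' @param features An `ap_features` row (or anything with the same fields).
#' @param rule_set `"text"` (procedure wording, default) or `"caption"`
#'   (figure wording).
#' @return A list of class `ap_class`: `label` (one of `"nodal"`,
#'   `"atrial"`, `"ventricular"`, `"unclassified"`) and `rule_trace`
#'   (character).
#' @export
classify <- function(features, rule_set = c("text", "caption")) {
  rule_set <- match.arg(rule_set)
  f <- as.list(features)
  need <- c("mdp", "apa", "dvdt_max", "apd90", "apd_ratio")
  if (!all(vapply(f[need], function(x) is.numeric(x) && is.finite(x), logical(1))))
    sm_stop("invalid_input", "incomplete features: need finite %s", paste(need, collapse = ", "))
  tr <- character(0)
  note <- function(...) tr <<- c(tr, sprintf(...))
  nodal <- f$apa < 100 && f$mdp > -50 && f$dvdt_max < 5
  note("nodal rule (APA < 100 & MDP > -50 & dV/dt_max < 5): %s", nodal)
  if (rule_set == "text") {
    working <- f$mdp < -55 && f$dvdt_max > 5
    note("working-myocyte gate (MDP < -55 & dV/dt_max > 5): %s", working)
    vent <- working && (f$apd90 > 400 || f$apd_ratio < 1.2)
    atr <- working && (f$apd90 < 300 || f$apd_ratio > 1.2)
    note("ventricular disjunction (APD90 > 400 | ratio < 1.2): %s", vent)
    note("atrial disjunction (APD90 < 300 | ratio > 1.2): %s", atr)
    label <- if (nodal && !(vent || atr)) "nodal"
      else if (vent && !atr && !nodal) "ventricular"
      else if (atr && !vent && !nodal) "atrial"
      else {
        if (vent && atr) note("conflict: both disjunctions fired; refusing to tie-break")
        if (!nodal && !vent && !atr) note("no rule fired (e.g. MDP in the -55..-50 mV gap)")
        "unclassified"
      }
  } else {
    working <- f$mdp < -60 && f$apa > 100 && f$dvdt_max > 5
    note("working-myocyte gate (MDP < -60 & APA > 100 & dV/dt_max > 5): %s", working)
    vent <- working && f$apd90 > 400 && f$apd_ratio < 1.2
    atr <- working && f$apd90 < 300 && f$apd_ratio > 1.2
    note("ventricular joint (APD90 > 400 & ratio < 1.2): %s", vent)
    note("atrial joint (APD90 < 300 & ratio > 1.2): %s", atr)
    label <- if (nodal && !vent && !atr) "nodal"
      else if (vent && !atr && !nodal) "ventricular"
      else if (atr && !vent && !nodal) "atrial"
      else {
        if (!nodal && !vent && !atr) note("no rule fired (e.g. MDP in the -60..-50 mV gap)")
        "unclassified"
      }
  }
  structure(list(label = label, rule_set = rule_set, rule_trace = tr),
            class = "ap_class")
}

#' @export
print.ap_class <- function(x, ...) {
  cat(sprintf("<ap_class> %s (%s rules)\n", x$label, x$rule_set))
  for (s in x$rule_trace) cat("  -", s, "\n")
  invisible(x)
}

#' Label proportions over a set of classified cells
#'
#' @param classes A list of `ap_class` objects (or a character vector of
#'   labels).
#' @return A tibble `(label, n, fraction)` over all four labels; fractions
#'   sum to 1.
#' @export
population_summary <- function(classes) {
  labels <- if (is.character(classes)) classes
            else vapply(classes, function(x) x$label, character(1))
  if (length(labels) == 0L)
    sm_stop("invalid_input", "empty class list")
  lv <- c("nodal", "atrial", "ventricular", "unclassified")
  n <- table(factor(labels, levels = lv))
  tibble::tibble(label = lv, n = as.integer(n),
                 fraction = as.numeric(n) / length(labels))
}
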