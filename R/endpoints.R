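# Protocol-level electrophysiological endpoints shared by the catheter,
# tissue-slice, MEA, and spiral arms: ERP from an S1-S2 capture scan,
# catheter conduction velocity over a fixed electrode span, and cohort
# summary tables of CV / duration / wavelength by group and side.

#' Effective refractory period from an S1-S2 capture scan
#'
#' The scan is a strictly decreasing series of S2 coupling intervals with a
#' capture flag each; capture must be present at the longest interval and,
#' once lost, must not return. The ERP convention is the longest
#' non-captured interval (the interval at loss of capture); the alternative
#' convention - the shortest captured interval - is available via
#' `convention` since the boundary interval is defined only to within one
#' decrement either way.
#'
#' @param scan A data.frame with `coupling_ms` (strictly decreasing) and
#'   logical `captured`, as returned by [simulate_s1s2()].
#' @param convention `"longest_noncapture"` (default) or
#'   `"shortest_capture"`.
#' @return A list of class `erp_result`: `erp_ms` (NA when capture is never
#'   lost), `reached` flag, `convention`, and the `scan`.
#' @export
erp_from_scan <- function(scan, convention = c("longest_noncapture", "shortest_capture")) {
  convention <- match.arg(convention)
  stopifnot(all(c("coupling_ms", "captured") %in% names(scan)))
  ci <- scan$coupling_ms
  cap <- scan$captured
  if (any(diff(ci) >= 0))
    sm_stop("protocol_violation", "coupling intervals must be strictly decreasing")
  if (!cap[1L])
    sm_stop("protocol_violation", "no capture at the longest coupling interval")
  if (any(diff(cap) > 0))
    sm_stop("protocol_violation", "capture returned after loss of capture")
  lost <- which(!cap)
  if (length(lost) == 0L) {
    return(structure(list(erp_ms = NA_real_, reached = FALSE,
                          convention = convention, scan = scan),
                     class = "erp_result"))
  }
  erp <- switch(convention,
                longest_noncapture = ci[lost[1L]],
                shortest_capture = ci[lost[1L] - 1L])
  structure(list(erp_ms = erp, reached = TRUE, convention = convention,
                 scan = scan),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  if (x$reached)
    cat(sprintf("<erp_result> ERP = %g ms (%s over %d intervals)\n",
                x$erp_ms, x$convention, nrow(x$scan)))
  else cat("<erp_result> ERP not reached (capture never lost)\n")
  invisible(x)
}

#' Conduction velocity from a catheter conduction time
#'
#' CV over the fixed recording span of a multipolar catheter (20 mm for a
#' decapolar array): span / conduction time.
#'
#' @param conduction_time_ms Conduction time over the span, ms (> 0).
#' @param span_mm Electrode span, mm.
#' @return CV, cm/s.
#' @export
#' @examples
#' catheter_cv(50)  # 40 cm/s
catheter_cv <- function(conduction_time_ms, span_mm = 20) {
  check_positive(conduction_time_ms, "conduction_time_ms")
  check_positive(span_mm, "span_mm")
  (span_mm / 10) / (conduction_time_ms / 1000)
}

#' Assemble an endpoint record
#'
#' One preparation's endpoints with provenance. The wavelength is computed
#' per record as CV x duration (so cohort means are means of per-subject
#' products, not products of means).
#'
#' @param source `"in_vivo"`, `"slice"`, `"mea"`, or `"spiral"`.
#' @param cv_cm_s Conduction velocity, cm/s.
#' @param duration_ms The duration endpoint, ms.
#' @param duration_type `"ERP"`, `"APD80"`, or `"APD90"`.
#' @param side `"LA"`, `"RA"`, or `"n/a"`.
#' @param group `"control"`, `"AF"`, or `"n/a"`.
#' @param drive_cycle_length_ms Pacing drive cycle length, ms (metadata).
#' @return A one-row tibble with a `wl_cm` column.
#' @export
endpoint_record <- function(source, cv_cm_s, duration_ms,
                            duration_type = c("ERP", "APD80", "APD90"),
                            side = "n/a", group = "n/a",
                            drive_cycle_length_ms = NA_real_) {
  source <- match.arg(source, c("in_vivo", "slice", "mea", "spiral"))
  duration_type <- match.arg(duration_type)
  side <- match.arg(side, c("LA", "RA", "n/a"))
  group <- match.arg(group, c("control", "AF", "n/a"))
  check_positive(cv_cm_s, "cv_cm_s")
  check_positive(duration_ms, "duration_ms")
  tibble::tibble(source = source, side = side, group = group,
                 cv_cm_s = cv_cm_s, duration_type = duration_type,
                 duration_ms = duration_ms,
                 wl_cm = wavelength_calculated(cv_cm_s, duration_ms),
                 drive_cycle_length_ms = drive_cycle_length_ms)
}

#' Cohort summary of endpoint records
#'
#' Mean and standard error of CV, duration, and wavelength per
#' (group, side, duration_type) cell, in long format. Cells with a single
#' record carry an NA standard error; requested groupings without records
#' are simply absent. Permutation-invariant in the record order.
#'
#' @param records A tibble of [endpoint_record()] rows.
#' @return A tibble `(group, side, duration_type, endpoint, n, mean, sem)`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L) sm_stop("invalid_input", "no records to summarise")
  long <- dplyr::bind_rows(
    dplyr::transmute(records, .data$group, .data$side, .data$duration_type,
                     endpoint = "cv_cm_s", value = .data$cv_cm_s),
    dplyr::transmute(records, .data$group, .data$side, .data$duration_type,
                     endpoint = "duration_ms", value = .data$duration_ms),
    dplyr::transmute(records, .data$group, .data$side, .data$duration_type,
                     endpoint = "wl_cm", value = .data$wl_cm)
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$side, .data$duration_type, .data$endpoint),
    n = dplyr::n(), mean = mean(.data$value), sem = sem(.data$value),
    .groups = "drop")
  dplyr::arrange(out, .data$group, .data$side, .data$duration_type, .data$endpoint)
}
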