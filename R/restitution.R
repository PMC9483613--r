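# Phenomenological restitution: single-exponential recovery of APD and CV
# with the preceding diastolic interval (DI), plus an absolute capture
# threshold on DI. This is the minimal monotone model needed to drive the
# S1-S2 extrastimulus protocol: a premature stimulus captures iff its
# diastolic interval reaches the threshold.

#' Create a restitution model
#'
#' APD(DI) = `apd_max * (1 - alpha_apd * exp(-DI / tau_apd))` and likewise
#' for CV; both are monotone non-decreasing in DI. A stimulus captures iff
#' its diastolic interval is at least `capture_threshold_di`.
#'
#' @param apd_max Asymptotic APD at long DI, ms.
#' @param cv_max Asymptotic CV, cm/s.
#' @param tau_apd,tau_cv Recovery time constants, ms.
#' @param alpha_apd,alpha_cv Fractional restitution depth in (0, 1).
#' @param capture_threshold_di Minimal DI that still captures, ms.
#' @return An object of class `restitution_model`.
#' @export
restitution_model <- function(apd_max = 250, cv_max = 30,
                              tau_apd = 60, tau_cv = 40,
                              alpha_apd = 0.35, alpha_cv = 0.5,
                              capture_threshold_di = 50) {
  check_positive(apd_max, "apd_max")
  check_positive(cv_max, "cv_max")
  check_positive(tau_apd, "tau_apd")
  check_positive(tau_cv, "tau_cv")
  check_nonnegative(capture_threshold_di, "capture_threshold_di")
  if (alpha_apd < 0 || alpha_apd >= 1 || alpha_cv < 0 || alpha_cv >= 1)
    sm_stop("invalid_parameter", "restitution depths must lie in [0, 1)")
  structure(list(apd_max = apd_max, cv_max = cv_max,
                 tau_apd = tau_apd, tau_cv = tau_cv,
                 alpha_apd = alpha_apd, alpha_cv = alpha_cv,
                 capture_threshold_di = capture_threshold_di),
            class = "restitution_model")
}

#' APD at a given diastolic interval, ms
#' @param model A `restitution_model`.
#' @param di Diastolic interval(s), ms (>= 0).
#' @return APD, ms.
#' @export
restitution_apd <- function(model, di) {
  model$apd_max * (1 - model$alpha_apd * exp(-pmax(di, 0) / model$tau_apd))
}

#' CV at a given diastolic interval, cm/s
#' @inheritParams restitution_apd
#' @return CV, cm/s.
#' @export
restitution_cv <- function(model, di) {
  model$cv_max * (1 - model$alpha_cv * exp(-pmax(di, 0) / model$tau_cv))
}

#' Steady-state APD under constant-cycle-length pacing
#'
#' Iterates APD_{i+1} = APD(CL - APD_i) for `n_beats` drive beats.
#' @param model A `restitution_model`.
#' @param cycle_length_ms Drive cycle length, ms.
#' @param n_beats Number of drive beats.
#' @return Steady-state APD, ms.
#' @export
restitution_steady_apd <- function(model, cycle_length_ms, n_beats = 10L) {
  apd <- model$apd_max * (1 - model$alpha_apd)
  for (i in seq_len(n_beats)) {
    di <- cycle_length_ms - apd
    if (di < model$capture_threshold_di)
      sm_stop("protocol_violation",
              "drive cycle length %g ms cannot sustain 1:1 capture", cycle_length_ms)
    apd <- restitution_apd(model, di)
  }
  apd
}

#' Simulate an S1-S2 extrastimulus scan
#'
#' A drive train of `s1_count` stimuli at `s1_cycle_length_ms` establishes
#' the steady-state APD; each S2 coupling interval in `s2_schedule_ms`
#' (strictly decreasing) then captures iff its diastolic interval
#' `S2 - APD_ss` reaches the model's capture threshold. Deterministic.
#'
#' @param model A `restitution_model`.
#' @param s1_cycle_length_ms S1 drive cycle length, ms.
#' @param s1_count Number of S1 beats.
#' @param s2_schedule_ms Strictly decreasing S2 coupling intervals, ms.
#' @return A tibble `(coupling_ms, captured)` with attributes `apd_ss`
#'   (steady-state APD) and `erp_continuum` (the exact refractory boundary
#'   `APD_ss + capture_threshold_di`, ms).
#' @export
simulate_s1s2 <- function(model, s1_cycle_length_ms = 1000, s1_count = 10L,
                          s2_schedule_ms = seq(600, 200, by = -10)) {
  if (any(diff(s2_schedule_ms) >= 0))
    sm_stop("invalid_parameter", "s2_schedule_ms must be strictly decreasing")
  apd_ss <- restitution_steady_apd(model, s1_cycle_length_ms, s1_count)
  di <- s2_schedule_ms - apd_ss
  out <- tibble::tibble(coupling_ms = as.numeric(s2_schedule_ms),
                        captured = di >= model$capture_threshold_di)
  attr(out, "apd_ss") <- apd_ss
  attr(out, "erp_continuum") <- apd_ss + model$capture_threshold_di
  out
}
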