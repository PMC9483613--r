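# Parametric action-potential template.
#
# The template is piecewise smooth with analytically invertible duration
# levels, so every simulated recording carries exact APD ground truth:
#   * linear upstroke from 0 to 1 over `t_up` ms;
#   * sigmoid repolarisation V(t) = R(t) / R(t_up),
#       R(t) = 1 / (1 + exp((t - t_half) / k)),
#     normalised so the peak value is exactly 1 at t = t_up.
# The repolarisation crossing of a normalised level v (0 < v < 1) is
#   t = t_half + k * log(1 / (v * R(t_up)) - 1),
# and the upstroke crossing of the same level is v * t_up, so
#   APD_p = t_half + k * log(1 / (v R(t_up)) - 1) - v * t_up,  v = 1 - p/100.
# `k` sets the repolarisation sharpness: small k gives the squarish optical
# action potential of processed voltage-dye data, larger k the gradual
# repolarisation of patch-clamp traces (APD90/APD50 ratio > 1).

.ap_R <- function(t, t_half, k) 1 / (1 + exp((t - t_half) / k))

#' Create an action-potential template
#'
#' Low-level constructor; most callers use [ap_template_optical()] (target
#' APD80) or [ap_template_patch()] (target APD90 and APD90/APD50 ratio, plus
#' amplitude, diastolic potential, and upstroke velocity).
#'
#' @param t_up Upstroke duration, ms.
#' @param t_half Repolarisation midpoint, ms from activation onset.
#' @param k Repolarisation time constant (sharpness), ms.
#' @param amplitude Peak-to-diastolic amplitude; 1 for normalised optical
#'   templates, the action-potential amplitude in mV for patch templates.
#' @param v_rest Diastolic (resting) level; 0 for optical, MDP in mV for patch.
#' @return An object of class `ap_template`.
#' @export
ap_template <- function(t_up, t_half, k, amplitude = 1, v_rest = 0) {
  check_positive(t_up, "t_up")
  check_positive(t_half, "t_half")
  check_positive(k, "k")
  check_positive(amplitude, "amplitude")
  if (t_half <= t_up)
    sm_stop("invalid_parameter", "t_half (%g ms) must exceed the upstroke duration (%g ms)",
            t_half, t_up)
  structure(list(t_up = t_up, t_half = t_half, k = k,
                 amplitude = amplitude, v_rest = v_rest),
            class = "ap_template")
}

#' Normalised template value at time t (ms after activation onset)
#'
#' Vectorised; 0 before onset, rises linearly to 1 at `t_up`, then follows
#' the normalised sigmoid repolarisation.
#' @param tmpl An `ap_template`.
#' @param t Times, ms.
#' @return Normalised voltage in [0, 1].
#' @export
ap_eval <- function(tmpl, t) {
  v <- numeric(length(t))
  up <- t >= 0 & t <= tmpl$t_up
  v[up] <- t[up] / tmpl$t_up
  re <- t > tmpl$t_up
  if (any(re))
    v[re] <- .ap_R(t[re], tmpl$t_half, tmpl$k) / .ap_R(tmpl$t_up, tmpl$t_half, tmpl$k)
  v
}

#' Template value for a periodic paced train
#'
#' Activation onsets at `t0 + i * cycle_length_ms`; the template support must
#' be shorter than the cycle length (enforced by the simulation configs).
#' @param tmpl An `ap_template`.
#' @param t Times, ms.
#' @param cycle_length_ms Pacing cycle length, ms.
#' @param t0 Time of the first activation, ms.
#' @return Normalised voltage.
#' @export
ap_train <- function(tmpl, t, cycle_length_ms, t0 = 0) {
  phase <- t - t0
  out <- numeric(length(t))
  act <- phase >= 0
  out[act] <- ap_eval(tmpl, phase[act] %% cycle_length_ms)
  out
}

#' Analytic action-potential duration of a template
#'
#' Duration at `p` percent repolarisation: time between the upstroke and
#' repolarisation crossings of the normalised level `1 - p/100`.
#' @param tmpl An `ap_template`.
#' @param p Repolarisation percentage (e.g. 80, 90, 50).
#' @return Duration, ms.
#' @export
template_apd <- function(tmpl, p) {
  v <- 1 - p / 100
  Rup <- .ap_R(tmpl$t_up, tmpl$t_half, tmpl$k)
  stopifnot(v * Rup < 1)
  t_rep <- tmpl$t_half + tmpl$k * log(1 / (v * Rup) - 1)
  t_rep - v * tmpl$t_up
}

#' Optical (voltage-dye) template with a prescribed APD80
#'
#' Squarish action potential appropriate for processed optical signals: the
#' repolarisation sharpness defaults to 1 ms so the durations measured at
#' different repolarisation levels are nearly equal, as for a propagating
#' wave whose spatial extent is read at 80% of maximal wave amplitude.
#'
#' @param apd80 Target APD80, ms.
#' @param t_up Upstroke duration, ms.
#' @param k Repolarisation sharpness, ms.
#' @return An `ap_template` whose [template_apd()] at 80 equals `apd80` to
#'   better than 1e-6 ms.
#' @export
ap_template_optical <- function(apd80, t_up = 3, k = 1) {
  check_positive(apd80, "apd80")
  f <- function(th) template_apd(ap_template(t_up, th, k), 80) - apd80
  th <- uniroot(f, c(t_up + 1e-3, apd80 + 10 * k + t_up + 10), tol = 1e-9)$root
  ap_template(t_up, th, k)
}

#' Patch-clamp template with prescribed APD90, APD90/APD50, APA, MDP, dV/dt max
#'
#' The upstroke duration follows from the amplitude and maximal upstroke
#' velocity (`t_up = APA / dVdt_max`, since mV/ms equals V/s numerically);
#' the repolarisation midpoint and sharpness are solved from the APD90 and
#' APD90/APD50 targets.
#'
#' @param apd90 Target APD90, ms.
#' @param apd_ratio Target APD90/APD50 (> 1).
#' @param apa Action-potential amplitude, mV.
#' @param mdp Minimal diastolic potential, mV.
#' @param dvdt_max Maximal upstroke velocity, V/s.
#' @return An `ap_template` (amplitude in mV, `v_rest` = MDP) reproducing the
#'   targets to better than 1e-6 ms.
#' @export
ap_template_patch <- function(apd90, apd_ratio, apa = 110, mdp = -64, dvdt_max = 27) {
  check_positive(apd90, "apd90")
  check_positive(apa, "apa")
  check_positive(dvdt_max, "dvdt_max")
  if (apd_ratio <= 1)
    sm_stop("invalid_parameter", "apd_ratio must exceed 1 (APD90 > APD50)")
  t_up <- apa / dvdt_max
  apd50 <- apd90 / apd_ratio
  if (apd50 <= 0.5 * t_up)
    sm_stop("invalid_parameter", "APD50 target shorter than half the upstroke")
  # fixed-point iteration on the closed-form crossings; R(t_up) ~ 1 so this
  # converges in a handful of steps, then durations are exact by construction
  Rup <- 1
  th <- apd50; k <- apd90 / 10
  for (i in 1:50) {
    A9 <- log(1 / (0.1 * Rup) - 1)
    A5 <- log(1 / (0.5 * Rup) - 1)
    k_new <- (apd90 - apd50 - 0.4 * t_up) / (A9 - A5)
    if (k_new <= 0)
      sm_stop("invalid_parameter", "infeasible APD90/APD50 combination for this upstroke")
    th_new <- apd50 + 0.5 * t_up - k_new * A5
    if (abs(th_new - th) < 1e-10 && abs(k_new - k) < 1e-10) break
    th <- th_new; k <- k_new
    Rup <- .ap_R(t_up, th, k)
  }
  ap_template(t_up, th, k, amplitude = apa, v_rest = mdp)
}

#' @export
print.ap_template <- function(x, ...) {
  cat(sprintf("<ap_template> t_up %.3g ms, t_half %.4g ms, k %.3g ms, amplitude %g, rest %g\n",
              x$t_up, x$t_half, x$k, x$amplitude, x$v_rest))
  cat(sprintf("  APD50 %.2f  APD80 %.2f  APD90 %.2f ms\n",
              template_apd(x, 50), template_apd(x, 80), template_apd(x, 90)))
  invisible(x)
}
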