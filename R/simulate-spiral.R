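# Kinematic simulator of voltage-dye recordings on the spiral pattern.
#
# Propagation is kinematic: the site at arc position x activates at
# |x - stim_arc| / cv after each stimulus and then plays the action-potential
# template. Voltage maps to fluorescence as
#   F = baseline * (1 + dye_fraction * V) * (1 - bleach_rate * t) + shot noise,
# i.e. a ~2% peak dF/F signal over a bright baseline with Gaussian noise
# proportional to baseline and a slow first-order photobleaching drift.
# Pixels outside the patterned line carry baseline, drift, and noise only.
# The closed-form ground truth (activation times, APD levels, wave extent
# cv * supra-threshold duration) is what the analysis chain is tested
# against.

#' Configuration for spiral voltage-dye simulations
#'
#' @param cv True conduction velocity, cm/s.
#' @param apd80 True APD80 of the optical action potential, ms.
#' @param cycle_length_ms Pacing cycle length, ms (500 ms = 2 Hz).
#' @param n_frames Number of full frames (300 frames at 30 fps = 10 s).
#' @param frame_rate Full-frame rate, Hz.
#' @param pixel_size um per pixel.
#' @param dye_fraction Peak dF/F of the voltage dye signal.
#' @param noise_sd Per-pixel Gaussian noise SD as a fraction of baseline.
#' @param bleach_rate Linear photobleaching drift, fraction of baseline per
#'   second.
#' @param baseline Baseline fluorescence, arbitrary units.
#' @param stim_arc Arc position of the stimulation electrode, cm.
#' @param upstroke_ms,sharpness_ms Optical template shape
#'   (see [ap_template_optical()]).
#' @param seed Integer seed; together with the config it fully determines
#'   the simulated output.
#' @param defects List of propagation defects: `list(type = "break",
#'   arc_cm = ...)` blocks conduction across that arc position;
#'   `list(type = "bridge", arc_cm = c(a, b))` connects two arc positions so
#'   each activates at the earlier of its own and its partner's time.
#' @return An object of class `spiral_sim_config`.
#' @export
spiral_sim_config <- function(cv = 20, apd80 = 180, cycle_length_ms = 500,
                              n_frames = 300L, frame_rate = 30,
                              pixel_size = 40, dye_fraction = 0.02,
                              noise_sd = 0.005, bleach_rate = 0.002,
                              baseline = 100, stim_arc = 0,
                              upstroke_ms = 3, sharpness_ms = 1,
                              seed = 1L, defects = list()) {
  check_positive(cv, "cv")
  check_positive(apd80, "apd80")
  check_positive(cycle_length_ms, "cycle_length_ms")
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_size, "pixel_size")
  check_nonnegative(noise_sd, "noise_sd")
  check_nonnegative(bleach_rate, "bleach_rate")
  check_nonnegative(stim_arc, "stim_arc")
  if (n_frames < 1L) sm_stop("invalid_parameter", "n_frames must be >= 1")
  if (apd80 >= cycle_length_ms)
    sm_stop("invalid_config",
            "apd80 (%g ms) must be shorter than the pacing cycle length (%g ms): waves would fuse",
            apd80, cycle_length_ms)
  for (d in defects) {
    if (!is.list(d) || is.null(d$type) || !d$type %in% c("break", "bridge"))
      sm_stop("invalid_parameter", "each defect needs type 'break' or 'bridge'")
    if (d$type == "bridge" && length(d$arc_cm) != 2L)
      sm_stop("invalid_parameter", "a bridge defect needs two arc positions")
  }
  structure(list(cv = cv, apd80 = apd80, cycle_length_ms = cycle_length_ms,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 pixel_size = pixel_size, dye_fraction = dye_fraction,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 baseline = baseline, stim_arc = stim_arc,
                 upstroke_ms = upstroke_ms, sharpness_ms = sharpness_ms,
                 seed = as.integer(seed), defects = defects),
            class = "spiral_sim_config")
}

#' Activation-time function along the path, honouring defects
#'
#' Breaks partition the path into segments that conduction cannot cross;
#' bridges connect two arc positions with zero delay, after which the wave
#' re-propagates from the bridged site. Unreachable positions get +Inf.
#'
#' @param design A `spiral_design`.
#' @param config A `spiral_sim_config`.
#' @return A function mapping arc positions (cm) to first-beat activation
#'   times (ms).
#' @export
arc_activation_fun <- function(design, config) {
  L <- design$total_length_cm
  if (config$stim_arc > L)
    sm_stop("invalid_parameter", "stim_arc (%g cm) beyond the path end (%g cm)", config$stim_arc, L)
  breaks <- sort(unlist(lapply(config$defects, function(d)
    if (d$type == "break") d$arc_cm else NULL)))
  bridges <- Filter(function(d) d$type == "bridge", config$defects)
  seg_of <- function(x) findInterval(x, breaks)
  ms_per_cm <- 1000 / config$cv
  function(arc_cm) {
    t_from <- function(src_pos, src_t, x) {
      tt <- src_t + abs(x - src_pos) * ms_per_cm
      tt[seg_of(x) != seg_of(src_pos)] <- Inf
      tt
    }
    sources <- list(list(pos = config$stim_arc, t = 0))
    eval_t <- function(x) {
      t_best <- rep(Inf, length(x))
      for (s in sources) t_best <- pmin(t_best, t_from(s$pos, s$t, x))
      t_best
    }
    # relax bridge endpoints until stable (zero-delay connections)
    for (it in seq_len(length(bridges) + 1L)) {
      changed <- FALSE
      for (bdg in bridges) {
        tt <- eval_t(bdg$arc_cm)
        tmin <- min(tt)
        if (is.finite(tmin) && tmin < max(tt) - 1e-12) {
          sources <- c(sources,
                       list(list(pos = bdg$arc_cm[1L], t = tmin),
                            list(pos = bdg$arc_cm[2L], t = tmin)))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    eval_t(arc_cm)
  }
}

#' Construct a frame-stack container
#'
#' @param intensities Numeric array `rows x cols x frames`, non-negative.
#' @param frame_rate Frames per second.
#' @param pixel_size um per pixel.
#' @param design_id Optional identifier of the pattern design.
#' @param truth Optional list of simulation ground truth (kept as metadata).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(intensities, frame_rate, pixel_size,
                        design_id = NULL, truth = NULL) {
  if (length(dim(intensities)) != 3L)
    sm_stop("invalid_parameter", "intensities must be a rows x cols x frames array")
  if (dim(intensities)[3L] < 1L)
    sm_stop("invalid_parameter", "frame stack needs at least one frame")
  if (min(intensities) < 0)
    sm_stop("invalid_parameter", "fluorescence intensities must be non-negative")
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_size, "pixel_size")
  structure(list(intensities = intensities, frame_rate = frame_rate,
                 pixel_size = pixel_size, design_id = design_id,
                 truth = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %g fps, %g um/px\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Simulate a full-frame voltage-dye recording of a spiral assay
#'
#' Renders the kinematic wave model on the rasterized pattern as a
#' fluorescence image stack. Waves repeat at the pacing cycle length; the
#' seed fully determines the output.
#'
#' @param design A `spiral_design`.
#' @param config A `spiral_sim_config`.
#' @return A [frame_stack()] whose `truth` records the config, the template
#'   durations, and the activation-time function inputs.
#' @export
simulate_spiral_recording <- function(design, config) {
  stopifnot(inherits(config, "spiral_sim_config"))
  msk <- rasterize_mask(design, config$pixel_size)
  tmpl <- ap_template_optical(config$apd80, config$upstroke_ms, config$sharpness_ms)
  if (template_apd(tmpl, 99.5) >= config$cycle_length_ms)
    sm_stop("invalid_config", "action potential tail reaches the next cycle (fusion)")
  t_act <- arc_activation_fun(design, config)(msk$arc_cm)
  nf <- config$n_frames
  tf <- (seq_len(nf) - 1L) / config$frame_rate * 1000
  bleach <- 1 - config$bleach_rate * tf / 1000
  nr <- msk$image_shape[1L]; nc <- msk$image_shape[2L]
  withr::with_seed(config$seed, {
    A <- tcrossprod(rep(config$baseline, nr * nc), bleach)
    A <- A + rnorm(length(A), sd = config$noise_sd * config$baseline)
    # template playback on the patterned pixels
    phase <- outer(-t_act, tf, "+")
    V <- matrix(0, length(t_act), nf)
    on <- is.finite(phase) & phase >= 0
    V[on] <- ap_eval(tmpl, phase[on] %% config$cycle_length_ms)
    sig <- config$baseline * (1 + config$dye_fraction * V) *
      matrix(bleach, nrow = length(t_act), ncol = nf, byrow = TRUE) +
      rnorm(length(V), sd = config$noise_sd * config$baseline)
    A[msk$pixel_idx, ] <- sig
  })
  A[A < 0] <- 0
  frame_stack(array(A, dim = c(nr, nc, nf)),
              frame_rate = config$frame_rate, pixel_size = config$pixel_size,
              design_id = sprintf("spiral_%g_%g_%g", design$d_l, design$d_s, design$n_turns),
              truth = list(config = config,
                           apd80 = template_apd(tmpl, 80),
                           supra80_duration_ms = supra_level_duration(tmpl, 0.8),
                           cv = config$cv))
}

#' Duration for which the template exceeds a normalised level
#'
#' Closed form: time between the upstroke and repolarisation crossings of
#' `level`; for a squarish optical template with level 0.8 this is the
#' temporal footprint of the supra-80% wave region.
#' @param tmpl An `ap_template`.
#' @param level Normalised level in (0, 1).
#' @return Duration, ms.
#' @export
supra_level_duration <- function(tmpl, level) {
  Rup <- .ap_R(tmpl$t_up, tmpl$t_half, tmpl$k)
  t_rep <- tmpl$t_half + tmpl$k * log(1 / (level * Rup) - 1)
  t_rep - level * tmpl$t_up
}

#' Simulate paired line-scan traces at two regions of the path
#'
#' The line-scan resonant mode trades spatial coverage for temporal
#' resolution: each trace is the mean fluorescence over an arc interval,
#' sampled at `frame_rate` (150 Hz by default). Noise is reduced by the
#' square root of the number of pixels averaged in the region.
#'
#' @param design A `spiral_design`.
#' @param config A `spiral_sim_config` (the full-frame config supplies the
#'   truth, noise, and duration; duration = `n_frames / frame_rate` of the
#'   full-frame recording).
#' @param region_a,region_b Arc intervals `c(lo, hi)` in cm, disjoint and
#'   within the path.
#' @param frame_rate Line-scan sampling rate, Hz.
#' @return A list of class `linescan_pair`: tibbles `trace_a` and `trace_b`
#'   (`time_ms`, `value`), `frame_rate`, `separation_cm` (between region
#'   centers), and `truth`.
#' @export
simulate_linescan <- function(design, config, region_a, region_b, frame_rate = 150) {
  stopifnot(inherits(config, "spiral_sim_config"))
  L <- design$total_length_cm
  for (r in list(region_a, region_b)) {
    if (length(r) != 2L || r[1L] >= r[2L] || r[1L] < 0 || r[2L] > L)
      sm_stop("invalid_parameter", "regions must be increasing intervals within [0, %.3f] cm", L)
  }
  if (max(region_a[1L], region_b[1L]) < min(region_a[2L], region_b[2L]))
    sm_stop("invalid_parameter", "line-scan regions must be disjoint")
  tmpl <- ap_template_optical(config$apd80, config$upstroke_ms, config$sharpness_ms)
  act <- arc_activation_fun(design, config)
  duration_ms <- config$n_frames / config$frame_rate * 1000
  nt <- floor(duration_ms / 1000 * frame_rate)
  tt <- (seq_len(nt) - 1L) / frame_rate * 1000
  bleach <- 1 - config$bleach_rate * tt / 1000
  px_cm <- config$pixel_size / 1e4
  one_region <- function(region) {
    arcs <- seq(region[1L], region[2L], by = px_cm)
    ta <- act(arcs)
    phase <- outer(tt, ta, "-")
    V <- matrix(0, nt, length(arcs))
    on <- is.finite(phase) & phase >= 0
    V[on] <- ap_eval(tmpl, phase[on] %% config$cycle_length_ms)
    vbar <- rowMeans(V)
    n_px <- max(1, diff(region) * (design$d_l / 1e4) / px_cm^2)
    noise <- rnorm(nt, sd = config$noise_sd * config$baseline / sqrt(n_px))
    tibble::tibble(
      time_ms = tt,
      value = config$baseline * (1 + config$dye_fraction * vbar) * bleach + noise
    )
  }
  withr::with_seed(config$seed + 1L, {
    a <- one_region(region_a)
    b <- one_region(region_b)
  })
  ta_mean <- mean(act(seq(region_a[1L], region_a[2L], length.out = 11L)))
  tb_mean <- mean(act(seq(region_b[1L], region_b[2L], length.out = 11L)))
  structure(list(
    trace_a = a, trace_b = b, frame_rate = frame_rate,
    separation_cm = abs(mean(region_b) - mean(region_a)),
    truth = list(cv = config$cv, apd80 = template_apd(tmpl, 80),
                 travel_time_ms = tb_mean - ta_mean)
  ), class = "linescan_pair")
}
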