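# Synthetic generators for the non-spiral recording modalities: 8x8
# microelectrode-array (MEA) field potentials, tissue-slice style optical
# map stacks, and single-cell patch-clamp traces.

# normalised template with a prescribed APD90, APD90/APD50 and upstroke
.ap_template_norm <- function(apd90, apd_ratio, t_up = 2) {
  p <- ap_template_patch(apd90, apd_ratio, apa = 100, mdp = 0, dvdt_max = 100 / t_up)
  ap_template(p$t_up, p$t_half, p$k, amplitude = 1, v_rest = 0)
}

#' Simulate an 8x8 MEA recording
#'
#' Electrode (row, col) sits at plane position `((col-1), (row-1)) * pitch`.
#' Either a planar wave travelling at `cv` along `direction_deg` (0 deg =
#' along rows, increasing column), or a point-source wave spreading
#' isotropically from the `origin` electrode (the stimulated corner). Each
#' electrode records a biphasic extracellular deflection whose maximal
#' negative slope falls exactly at the true activation time.
#'
#' @param cv True conduction velocity, cm/s.
#' @param mode `"point_source"` (stimulation at `origin`) or `"planar"`.
#' @param direction_deg Propagation direction for planar mode, degrees.
#' @param origin Stimulated electrode `(row, col)` for point-source mode.
#' @param electrode_pitch Electrode spacing, um.
#' @param grid_dim Grid dimensions, electrodes.
#' @param sample_rate Sampling rate, Hz.
#' @param n_beats,cycle_length_ms Pacing.
#' @param spike_sigma_ms Width of the extracellular deflection, ms.
#' @param noise_sd Gaussian noise SD in units of the spike amplitude.
#' @param seed Integer seed.
#' @return An object of class `mea_recording`: `traces` (time x electrode,
#'   electrodes column-major by grid), `time_ms`, grid metadata, and
#'   `truth$activation_ms` (true first-beat activation matrix).
#' @export
simulate_mea <- function(cv = 9, mode = c("point_source", "planar"),
                         direction_deg = 0, origin = c(1L, 1L),
                         electrode_pitch = 450, grid_dim = c(8L, 8L),
                         sample_rate = 10000, n_beats = 2L,
                         cycle_length_ms = 500, spike_sigma_ms = 2,
                         noise_sd = 0, seed = 1L) {
  check_positive(cv, "cv")
  mode <- match.arg(mode)
  nr <- grid_dim[1L]; nc <- grid_dim[2L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- (cols - 1) * electrode_pitch  # um
  y <- (rows - 1) * electrode_pitch
  um_per_ms <- cv * 10  # cm/s -> um/ms
  if (mode == "planar") {
    th <- direction_deg * pi / 180
    proj <- x * cos(th) + y * sin(th)
    t_act <- (proj - min(proj)) / um_per_ms
  } else {
    dx <- x - (origin[2L] - 1) * electrode_pitch
    dy <- y - (origin[1L] - 1) * electrode_pitch
    t_act <- sqrt(dx^2 + dy^2) / um_per_ms
  }
  t0 <- 20
  duration_ms <- t0 + (n_beats - 1L) * cycle_length_ms + max(t_act) + 8 * spike_sigma_ms
  nt <- ceiling(duration_ms / 1000 * sample_rate)
  tt <- (seq_len(nt) - 1L) / sample_rate * 1000
  traces <- matrix(0, nt, nr * nc)
  for (e in seq_len(nr * nc)) {
    v <- numeric(nt)
    for (b in seq_len(n_beats)) {
      centre <- t0 + (b - 1L) * cycle_length_ms + t_act[e] + spike_sigma_ms
      v <- v - exp(-(tt - centre)^2 / (2 * spike_sigma_ms^2))
    }
    traces[, e] <- v
  }
  if (noise_sd > 0)
    traces <- traces + withr::with_seed(seed, matrix(rnorm(length(traces), sd = noise_sd),
                                                     nrow = nt))
  structure(list(traces = traces, time_ms = tt, sample_rate = sample_rate,
                 electrode_pitch = electrode_pitch, grid_dim = grid_dim,
                 stim_electrode = if (mode == "point_source") origin else NULL,
                 truth = list(cv = cv, mode = mode,
                              activation_ms = t_act + t0)),
            class = "mea_recording")
}

#' Simulate a tissue-slice style optical mapping stack
#'
#' A wave spreads from the field centre (point source) or as a plane wave,
#' with elliptical anisotropy: `cv_long` along `angle_deg` and `cv_trans`
#' across it. Voltage maps to fluorescence exactly as in the spiral
#' simulator.
#'
#' @param cv_long,cv_trans Longitudinal and transverse CV, cm/s.
#' @param angle_deg Fibre (fast) direction, degrees.
#' @param apd90,apd_ratio Action-potential shape targets.
#' @param nx,ny Field size, pixels (100 x 100 spanning the 1 cm field of a
#'   typical optical-mapping sensor).
#' @param pixel_size um per pixel.
#' @param frame_rate Hz (optical mapping cameras run well above 300 Hz).
#' @param mode `"point_source"` or `"planar"` (planar travels at `cv_long`
#'   along `angle_deg`).
#' @param dye_fraction,noise_sd,bleach_rate,baseline As in
#'   [spiral_sim_config()].
#' @param seed Integer seed.
#' @return A [frame_stack()] with `truth` holding the activation-time matrix
#'   and the template durations.
#' @export
simulate_slice_stack <- function(cv_long = 50, cv_trans = 25, angle_deg = 0,
                                 apd90 = 240, apd_ratio = 1.3,
                                 nx = 100L, ny = 100L, pixel_size = 100,
                                 frame_rate = 1000,
                                 mode = c("point_source", "planar"),
                                 dye_fraction = 0.05, noise_sd = 0.002,
                                 bleach_rate = 0.005, baseline = 100,
                                 seed = 1L) {
  mode <- match.arg(mode)
  check_positive(cv_long, "cv_long"); check_positive(cv_trans, "cv_trans")
  tmpl <- .ap_template_norm(apd90, apd_ratio, t_up = 5)
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  x <- (cols - (nx + 1) / 2) * pixel_size
  y <- (rows - (ny + 1) / 2) * pixel_size
  th <- angle_deg * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  vl <- cv_long * 10; vt <- cv_trans * 10  # um/ms
  t_act <- if (mode == "point_source") {
    sqrt((xr / vl)^2 + (yr / vt)^2)
  } else {
    (xr - min(xr)) / vl
  }
  t0 <- 10
  duration_ms <- t0 + max(t_act) + template_apd(tmpl, 99) + 150
  nt <- ceiling(duration_ms / 1000 * frame_rate)
  tt <- (seq_len(nt) - 1L) / frame_rate * 1000
  bleach <- 1 - bleach_rate * tt / 1000
  phase <- outer(c(t_act) + t0, tt, FUN = function(a, b) b - a)
  V <- matrix(0, length(t_act), nt)
  on <- phase >= 0
  V[on] <- ap_eval(tmpl, phase[on])
  A <- baseline * (1 + dye_fraction * V) *
    matrix(bleach, nrow = length(t_act), ncol = nt, byrow = TRUE)
  if (noise_sd > 0)
    A <- A + withr::with_seed(seed, matrix(rnorm(length(A), sd = noise_sd * baseline),
                                           nrow = nrow(A)))
  A[A < 0] <- 0
  frame_stack(array(A, dim = c(ny, nx, nt)), frame_rate = frame_rate,
              pixel_size = pixel_size,
              truth = list(cv_long = cv_long, cv_trans = cv_trans,
                           angle_deg = angle_deg, mode = mode,
                           activation_ms = matrix(t_act + t0, ny, nx),
                           apd90 = template_apd(tmpl, 90)))
}

#' Simulate a patch-clamp action-potential trace
#'
#' A paced train of template action potentials in mV over ms, preceded by a
#' diastolic segment at the MDP. The extracted features
#' ([extract_features()]) match the nominal parameters to within one sample.
#'
#' @param mdp Minimal diastolic potential, mV.
#' @param apa Action-potential amplitude, mV.
#' @param dvdt_max Maximal upstroke velocity, V/s.
#' @param apd90 APD90, ms.
#' @param apd_ratio APD90/APD50.
#' @param cycle_length_ms Pacing cycle length, ms.
#' @param n_beats Number of action potentials.
#' @param sample_rate Sampling rate, Hz (>= 1 kHz).
#' @param noise_sd_mv Gaussian noise SD, mV.
#' @param seed Integer seed (used only when `noise_sd_mv > 0`).
#' @return A tibble `(time_ms, voltage_mv)` with a `truth` attribute.
#' @export
simulate_patch_ap <- function(mdp = -63.9, apa = 110, dvdt_max = 27.1,
                              apd90 = 294.6, apd_ratio = 1.34,
                              cycle_length_ms = 1000, n_beats = 3L,
                              sample_rate = 5000, noise_sd_mv = 0, seed = 1L) {
  tmpl <- ap_template_patch(apd90, apd_ratio, apa = apa, mdp = mdp,
                            dvdt_max = dvdt_max)
  t0 <- 100
  duration_ms <- t0 + n_beats * cycle_length_ms
  nt <- ceiling(duration_ms / 1000 * sample_rate)
  tt <- (seq_len(nt) - 1L) / sample_rate * 1000
  v <- mdp + apa * ap_train(tmpl, tt, cycle_length_ms, t0 = t0)
  if (noise_sd_mv > 0)
    v <- v + withr::with_seed(seed, rnorm(nt, sd = noise_sd_mv))
  out <- tibble::tibble(time_ms = tt, voltage_mv = v)
  attr(out, "truth") <- list(mdp = mdp, apa = apa, dvdt_max = dvdt_max,
                             apd90 = template_apd(tmpl, 90),
                             apd50 = template_apd(tmpl, 50),
                             apd_ratio = template_apd(tmpl, 90) / template_apd(tmpl, 50))
  out
}

# rejection sampler for a truncated normal
.rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Simulate a population of patch-clamped cardiomyocytes
#'
#' Draws per-cell action-potential parameters from three truncated-normal
#' subtype distributions (atrial, ventricular, nodal) whose supports respect
#' the text classification rules, simulates each trace, and returns the
#' traces alongside the true labels, so classifier recovery of the mixing
#' fractions can be checked against the generator's ground truth.
#'
#' @param n Number of cells.
#' @param mix Named mixing fractions for `atrial`, `ventricular`, `nodal`
#'   (normalised internally).
#' @param sample_rate Hz.
#' @param noise_sd_mv Trace noise, mV.
#' @param seed Integer seed.
#' @return A list: `cells` tibble (true parameters and `true_class`) and
#'   `traces` (list of `(time_ms, voltage_mv)` tibbles).
#' @export
simulate_patch_population <- function(n = 30L,
                                      mix = c(atrial = 0.6, ventricular = 0.25, nodal = 0.15),
                                      sample_rate = 2000, noise_sd_mv = 0.5,
                                      seed = 1L) {
  mix <- mix / sum(mix)
  withr::with_seed(seed, {
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    draw <- function(cl) {
      switch(cl,
        atrial = list(mdp = .rtrunc(1, -64, 2, hi = -58),
                      apa = .rtrunc(1, 110, 5, lo = 103),
                      dvdt = .rtrunc(1, 27, 5, lo = 8),
                      apd90 = .rtrunc(1, 265, 15, lo = 180, hi = 292),
                      ratio = .rtrunc(1, 1.38, 0.05, lo = 1.26)),
        ventricular = list(mdp = .rtrunc(1, -70, 3, hi = -62),
                           apa = .rtrunc(1, 115, 5, lo = 103),
                           dvdt = .rtrunc(1, 50, 8, lo = 8),
                           apd90 = .rtrunc(1, 550, 60, lo = 430),
                           ratio = .rtrunc(1, 1.10, 0.03, lo = 1.03, hi = 1.17)),
        nodal = list(mdp = .rtrunc(1, -45, 2, lo = -48, hi = -40),
                     apa = .rtrunc(1, 85, 5, hi = 96),
                     dvdt = .rtrunc(1, 2.5, 1, lo = 1, hi = 3.8),
                     apd90 = .rtrunc(1, 250, 30, lo = 150),
                     ratio = .rtrunc(1, 1.5, 0.1, lo = 1.3)))
    }
    cells <- do.call(rbind, lapply(classes, function(cl) {
      p <- draw(cl)
      data.frame(true_class = cl, mdp = p$mdp, apa = p$apa, dvdt_max = p$dvdt,
                 apd90 = p$apd90, apd_ratio = p$ratio)
    }))
    seeds <- sample.int(1e6, n)
  })
  traces <- lapply(seq_len(n), function(i) {
    simulate_patch_ap(mdp = cells$mdp[i], apa = cells$apa[i],
                      dvdt_max = cells$dvdt_max[i], apd90 = cells$apd90[i],
                      apd_ratio = cells$apd_ratio[i],
                      cycle_length_ms = max(1000, cells$apd90[i] * 2.2),
                      n_beats = 2L, sample_rate = sample_rate,
                      noise_sd_mv = noise_sd_mv, seed = seeds[i])
  })
  list(cells = tibble::as_tibble(cells), traces = traces)
}
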