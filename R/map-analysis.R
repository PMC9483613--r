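# 2D conduction analyses: preprocessing of tissue-slice optical-map stacks,
# activation maps at 50% of upstroke amplitude, APD90 maps with the
# below-baseline motion-artifact flag, plane-fit velocity fields with
# longitudinal / transverse CV, and the averaged corner-vector CV of an 8x8
# MEA conduction map.

#' Preprocess a tissue-slice optical-map stack
#'
#' Standard optical-mapping conditioning: temporal low-pass (default 150 Hz,
#' clipped below Nyquist with a warning), 7x7 boxcar spatial averaging,
#' per-pixel min-max normalisation to [0, 1], and per-pixel first-order
#' (linear) detrending of fluorescence drift. Pixels whose pre-normalisation
#' amplitude does not clear `snr_min` times the noise floor are flagged
#' invalid.
#'
#' @param stack A [frame_stack()].
#' @param lowpass_hz Temporal cutoff, Hz.
#' @param spatial_px Boxcar window, pixels.
#' @param snr_min Minimal amplitude / noise-floor ratio for a valid pixel.
#' @param drift_min Minimal fitted drift (fraction of the normalised range)
#'   for the first-order drift removal to be applied to a pixel.
#' @return A list of class `slice_stack`: normalised `intensities`
#'   (rows x cols x frames), `frame_rate`, `pixel_size`, logical `valid`
#'   (rows x cols), `degenerate` flag matrix (pixels with zero range).
#' @export
slice_preprocess <- function(stack, lowpass_hz = 150, spatial_px = 7L, snr_min = 5,
                             drift_min = 0.1) {
  stopifnot(inherits(stack, "frame_stack"))
  dims <- dim(stack$intensities)
  if (dims[3L] < 2L) sm_stop("invalid_input", "stack shorter than 2 frames")
  fr <- stack$frame_rate
  w <- 2 * lowpass_hz / fr
  if (w >= 1) {
    sm_warn("cutoff_clipped",
            "temporal cutoff %g Hz at or above Nyquist (%g Hz); clipped", lowpass_hz, fr / 2)
    w <- 0.9
  }
  nr <- dims[1L]; nc <- dims[2L]; nf <- dims[3L]
  M <- matrix(stack$intensities, nr * nc, nf)
  noise <- apply(M, 1L, noise_floor)
  bf <- signal::butter(3L, w, type = "low")
  Mf <- t(apply(M, 1L, zero_phase_filter, b = bf$b, a = bf$a))
  # 7x7 spatial boxcar, frame by frame
  for (f in seq_len(nf)) {
    Mf[, f] <- c(box_mean(matrix(Mf[, f], nr, nc), spatial_px))
  }
  rng_lo <- apply(Mf, 1L, min)
  rng_hi <- apply(Mf, 1L, max)
  rng <- rng_hi - rng_lo
  # relative threshold: numerical dust on a constant pixel must not be
  # amplified to full scale by the min-max normalisation
  degenerate <- rng <= 1e-6 * pmax(abs(rng_hi), 1)
  valid <- !degenerate & rng > snr_min * pmax(noise, .Machine$double.eps)
  Mn <- (Mf - rng_lo) / ifelse(degenerate, 1, rng)
  Mn[degenerate, ] <- 0
  # first-order drift removal, applied to all pixels or to none (decided by
  # the median fitted drift across valid pixels): the diastolic anchor is
  # not perfectly free of repolarisation-tail samples, so detrending an
  # essentially drift-free stack injects small position-dependent tilts
  # that bias downstream gradient fits, and mixing detrended with
  # untouched pixels is worse still
  live <- which(!degenerate)
  if (length(live) > 0L) {
    trends <- lapply(live, function(i) fit_diastolic_trend(Mn[i, ]))
    drift <- vapply(trends, function(tr) diff(range(tr)), numeric(1))
    if (median(drift) > drift_min)
      for (k in seq_along(live)) Mn[live[k], ] <- Mn[live[k], ] - trends[[k]]
  }
  structure(list(intensities = array(Mn, dim = dims), frame_rate = fr,
                 pixel_size = stack$pixel_size,
                 valid = matrix(valid, nr, nc),
                 degenerate = matrix(degenerate, nr, nc)),
            class = "slice_stack")
}

#' Activation map at 50% of upstroke amplitude
#'
#' Per valid pixel, the activation time is the sub-sample interpolated first
#' upstroke crossing of 50% of that pixel's action-potential amplitude.
#'
#' @param stack A `slice_stack` from [slice_preprocess()], or a
#'   [frame_stack()] (preprocessed on the fly).
#' @param mode Activation definition; only `"upstroke50"` is provided.
#' @return An object of class `activation_map`: `activation_ms`
#'   (rows x cols), logical `valid`, `spacing_um`.
#' @export
activation_map <- function(stack, mode = c("upstroke50")) {
  match.arg(mode)
  if (inherits(stack, "frame_stack")) stack <- slice_preprocess(stack)
  stopifnot(inherits(stack, "slice_stack"))
  dims <- dim(stack$intensities)
  nr <- dims[1L]; nc <- dims[2L]; nf <- dims[3L]
  tt <- (seq_len(nf) - 1L) / stack$frame_rate * 1000
  M <- matrix(stack$intensities, nr * nc, nf)
  act <- rep(NA_real_, nr * nc)
  for (i in which(c(stack$valid))) {
    v <- M[i, ]
    b <- quantile(v, 0.05, names = FALSE)
    level <- b + 0.5 * (max(v) - b)
    cr <- level_crossings(tt, v, level, "up")
    if (length(cr) == 0L) next
    # refine with a monotone spline through the samples around the
    # crossing: linear interpolation across the curved upstroke leaves a
    # periodic sub-sample ripple that biases downstream gradient fits
    k <- findInterval(cr[1L], tt)
    win <- max(1L, k - 2L):min(nf, k + 3L)
    act[i] <- if (length(win) >= 4L && all(diff(v[win]) >= 0)) {
      sf <- stats::splinefun(tt[win], v[win], method = "hyman")
      uniroot(function(z) sf(z) - level, range(tt[win]), tol = 1e-8)$root
    } else cr[1L]
  }
  valid <- stack$valid & matrix(is.finite(act), nr, nc)
  structure(list(activation_ms = matrix(act, nr, nc), valid = valid,
                 spacing_um = stack$pixel_size),
            class = "activation_map")
}

#' Construct an activation map from known times
#'
#' @param activation_ms Matrix of activation times, ms.
#' @param spacing_um Site spacing, um.
#' @param valid Logical matrix; defaults to finite times.
#' @return An `activation_map`.
#' @export
make_activation_map <- function(activation_ms, spacing_um, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(activation_ms)
  structure(list(activation_ms = activation_ms, valid = valid,
                 spacing_um = spacing_um),
            class = "activation_map")
}

#' APD90 map of a preprocessed slice stack
#'
#' Per valid pixel the APD90 of the first complete action potential, as in
#' [extract_features()] but at the 90% repolarisation level only. Pixels
#' whose trace dips below the diastolic baseline by more than 10% of the
#' amplitude are flagged as motion artifacts and excluded.
#'
#' @param stack A `slice_stack` (or `frame_stack`, preprocessed on the fly).
#' @return A list of class `apd_map`: `apd90_ms` matrix, logical `valid`,
#'   logical `artifact`.
#' @export
apd90_map <- function(stack) {
  if (inherits(stack, "frame_stack")) stack <- slice_preprocess(stack)
  stopifnot(inherits(stack, "slice_stack"))
  dims <- dim(stack$intensities)
  nr <- dims[1L]; nc <- dims[2L]; nf <- dims[3L]
  tt <- (seq_len(nf) - 1L) / stack$frame_rate * 1000
  M <- matrix(stack$intensities, nr * nc, nf)
  apd <- rep(NA_real_, nr * nc)
  artifact <- rep(FALSE, nr * nc)
  for (i in which(c(stack$valid))) {
    v <- M[i, ]
    aps <- tryCatch(detect_aps(tt, v, min_separation_ms = 50), error = function(e) NULL)
    if (is.null(aps)) next
    ap <- aps[1L, ]
    amp <- ap$peak - ap$base
    if (min(v) < ap$base - 0.1 * amp) { artifact[i] <- TRUE; next }
    apd[i] <- ap_duration(tt, v, ap, 90)
  }
  valid <- stack$valid & matrix(is.finite(apd), nr, nc)
  if (!any(valid))
    sm_stop("empty_map", "no artifact-free pixel with a measurable APD90")
  structure(list(apd90_ms = matrix(apd, nr, nc), valid = valid,
                 artifact = matrix(artifact, nr, nc)),
            class = "apd_map")
}

#' Local conduction-velocity vectors by sliding plane fits
#'
#' Least-squares plane fit of activation time over sliding `window` x
#' `window` neighbourhoods of valid sites; speed = 1 / |gradient|, direction
#' along the time gradient.
#'
#' @param amap An `activation_map`.
#' @param window Neighbourhood size, sites (odd; 3 for MEA grids, 7 for
#'   optical maps).
#' @param min_valid Minimal valid sites per window.
#' @param min_r2 Minimal R-squared of the local plane fit. Windows where
#'   the activation surface is strongly curved (e.g. straddling a point
#'   source, where the true gradient vanishes and 1/|gradient| diverges)
#'   or dominated by timing quantisation are discarded.
#' @return A tibble: `row`, `col`, `speed_cm_s`, `angle_deg` (propagation
#'   direction, 0-180).
#' @export
cv_vector_field <- function(amap, window = 3L, min_valid = NULL, min_r2 = 0.95) {
  stopifnot(inherits(amap, "activation_map"))
  h <- window %/% 2L
  if (is.null(min_valid)) min_valid <- max(5L, ceiling(window^2 * 0.6))
  tmat <- amap$activation_ms
  nr <- nrow(tmat); nc <- ncol(tmat)
  rows <- list()
  for (r in (1L + h):(nr - h)) {
    for (cc in (1L + h):(nc - h)) {
      rs <- (r - h):(r + h); cs <- (cc - h):(cc + h)
      sub <- tmat[rs, cs]
      ok <- amap$valid[rs, cs] & is.finite(sub)
      if (sum(ok) < min_valid) next
      yy <- matrix(rs, window, window)[ok]
      xx <- matrix(cs, window, window, byrow = TRUE)[ok]
      zz <- sub[ok]
      xc <- xx - cc; yc <- yy - r
      # local quadratic surface; the gradient at the window centre is then
      # unbiased by wavefront curvature (a plane fit across a curved front
      # systematically under-reads |grad t| and so over-reads speed)
      X <- if (sum(ok) >= 8L) cbind(1, xc, yc, xc^2, xc * yc, yc^2)
           else cbind(1, xc, yc)
      g <- tryCatch(qr.coef(qr(X), zz), error = function(e) NULL)
      if (is.null(g) || any(!is.finite(g[2:3]))) next
      resid <- zz - X %*% g
      sst <- sum((zz - mean(zz))^2)
      if (sst < 1e-12 || 1 - sum(resid^2) / sst < min_r2) next
      gn <- sqrt(g[2L]^2 + g[3L]^2)  # ms per site
      if (gn < 1e-9) next
      speed <- amap$spacing_um / gn * 0.1  # um/ms -> cm/s
      ang <- (atan2(g[3L], g[2L]) * 180 / pi) %% 180
      rows[[length(rows) + 1L]] <- data.frame(row = r, col = cc,
                                              speed_cm_s = speed, angle_deg = ang)
    }
  }
  if (length(rows) == 0L)
    sm_stop("insufficient_data", "no window had enough valid sites for a plane fit")
  tibble::as_tibble(do.call(rbind, rows))
}

#' Longitudinal and transverse conduction velocity
#'
#' Bins the local velocity vectors by propagation direction (10 degree bins
#' over 0-180) and takes the median speed per sufficiently populated bin;
#' the longitudinal CV is the maximal bin median (with its direction), the
#' transverse CV the minimal. A plane-fit velocity-field method standing in
#' for dedicated optical-mapping packages.
#'
#' @param amap An `activation_map`.
#' @param window Plane-fit window (3 for electrode grids, 7 for pixel maps).
#' @param bin_deg Direction bin width, degrees.
#' @param min_per_bin Minimal vectors per bin.
#' @return A list: `longitudinal_cv`, `transverse_cv`, `angle_deg` (of the
#'   fast direction), `vectors` (the field), `bins` (per-bin medians).
#' @export
directional_cv <- function(amap, window = 7L, bin_deg = 10, min_per_bin = 3L) {
  vf <- cv_vector_field(amap, window = window)
  bins <- floor(vf$angle_deg / bin_deg)
  med <- tapply(vf$speed_cm_s, bins, median)
  cnt <- tapply(vf$speed_cm_s, bins, length)
  med <- med[cnt >= min_per_bin]
  if (length(med) == 0L)
    sm_stop("insufficient_data", "no direction bin has %d vectors", min_per_bin)
  i_max <- which.max(med); i_min <- which.min(med)
  list(longitudinal_cv = unname(med[i_max]),
       transverse_cv = unname(med[i_min]),
       angle_deg = (as.numeric(names(med)[i_max]) + 0.5) * bin_deg,
       vectors = vf,
       bins = tibble::tibble(angle_deg = (as.numeric(names(med)) + 0.5) * bin_deg,
                             median_speed = as.numeric(med)))
}

#' Activation map of an MEA recording
#'
#' Activation time per electrode is the time of maximal negative slope of
#' the field potential (sub-sample refined by parabolic interpolation of
#' the discrete derivative), the standard extracellular convention.
#'
#' @param rec An `mea_recording`.
#' @param smooth_ms Optional moving-median width for noisy traces, ms.
#' @return An `activation_map` over the electrode grid.
#' @export
mea_activation_map <- function(rec, smooth_ms = 0) {
  stopifnot(inherits(rec, "mea_recording"))
  nr <- rec$grid_dim[1L]; nc <- rec$grid_dim[2L]
  dt <- 1000 / rec$sample_rate
  act <- matrix(NA_real_, nr, nc)
  for (e in seq_len(nr * nc)) {
    v <- rec$traces[, e]
    if (smooth_ms > 0) v <- moving_median(v, max(3L, round(smooth_ms / dt)))
    dv <- diff(v)
    # first-beat deflection: earliest cluster of near-minimal slopes, so a
    # paced train cannot alias electrode times by one cycle
    cand <- which(dv <= 0.5 * min(dv))
    first <- cand[c(TRUE, diff(cand) > 1L)][1L]
    seg <- first:min(length(dv), first + ceiling(20 / dt))
    i <- seg[which.min(dv[seg])]
    # parabolic sub-sample refinement of the derivative minimum
    if (i > 1L && i < length(dv)) {
      y1 <- dv[i - 1L]; y2 <- dv[i]; y3 <- dv[i + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    } else delta <- 0
    act[e] <- (i - 0.5 + delta) * dt
  }
  make_activation_map(act, spacing_um = rec$electrode_pitch)
}

#' Mean monolayer CV from an MEA conduction map
#'
#' Three conduction vectors from the stimulated corner electrode - along its
#' row, along its column, and along the main diagonal - each divided by the
#' activation-time difference over the vector; the monolayer CV is their
#' mean. Vectors without a usable time difference are dropped with a
#' warning.
#'
#' @param amap An `activation_map` over the electrode grid.
#' @param stim_electrode `(row, col)` of the stimulated electrode.
#' @return The mean CV, cm/s, with attribute `vectors` (per-vector CVs).
#' @export
mea_mean_cv <- function(amap, stim_electrode = c(1L, 1L)) {
  stopifnot(inherits(amap, "activation_map"))
  tmat <- amap$activation_ms
  nr <- nrow(tmat); nc <- ncol(tmat)
  r0 <- stim_electrode[1L]; c0 <- stim_electrode[2L]
  far_r <- if (r0 <= nr / 2) nr else 1L
  far_c <- if (c0 <= nc / 2) nc else 1L
  p <- amap$spacing_um
  targets <- list(
    horizontal = list(end = c(r0, far_c), dist = abs(far_c - c0) * p),
    vertical = list(end = c(far_r, c0), dist = abs(far_r - r0) * p),
    diagonal = list(end = c(far_r, far_c),
                    dist = sqrt((far_r - r0)^2 + (far_c - c0)^2) * p)
  )
  cvs <- c()
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    t1 <- tmat[r0, c0]; t2 <- tmat[tg$end[1L], tg$end[2L]]
    if (!amap$valid[r0, c0] || !amap$valid[tg$end[1L], tg$end[2L]] ||
        !is.finite(t1) || !is.finite(t2) || abs(t2 - t1) < 1e-6) {
      sm_warn("vector_dropped", "%s vector unusable (missing or zero time difference)", nm)
      next
    }
    cvs[nm] <- tg$dist / abs(t2 - t1) * 0.1  # um/ms -> cm/s
  }
  if (length(cvs) == 0L)
    sm_stop("insufficient_data", "all conduction vectors were dropped")
  out <- mean(cvs)
  attr(out, "vectors") <- cvs
  out
}
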