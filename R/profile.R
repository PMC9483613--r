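# Along-path profile analysis of full-frame spiral recordings: extract the
# space x time intensity matrix along the patterned line, filter and
# normalise it, and measure the conduction wavelength directly as the arc
# extent of the wave at 80% of maximal wave amplitude.

#' Extract the fluorescence profile along the spiral path
#'
#' Intensity at arc position x is the mean over an `extraction_width`-pixel
#' wide cross-section normal to the centerline at x (bilinear interpolation
#' of the frame), evaluated for every frame.
#'
#' @param stack A [frame_stack()].
#' @param design The `spiral_design` registered to the frame geometry (the
#'   spiral centre at the image centre).
#' @param extraction_width Cross-section width, pixels.
#' @param arc_step_cm Arc sampling step, cm. The default of 0.001 cm
#'   (10 um) matches the native pixel pitch at which along-path profiles are
#'   drawn on the source images and keeps the spatial filter's transition
#'   band (~400 arc samples at the 0.005 normalised cutoff) short against
#'   the wave extent.
#' @return An object of class `path_profile`: `matrix` (arc x frame),
#'   `arc_cm`, `arc_step_cm`, `frame_rate`, `extraction_width`,
#'   `normalized` flag, and the path length `L_cm`.
#' @export
extract_path_profile <- function(stack, design, extraction_width = 10L,
                                 arc_step_cm = 0.001) {
  stopifnot(inherits(stack, "frame_stack"))
  validate_spiral_design(design)
  px <- stack$pixel_size
  check_positive(arc_step_cm, "arc_step_cm")
  dims <- dim(stack$intensities)
  nr <- dims[1L]; nc <- dims[2L]; nf <- dims[3L]
  image_shape <- c(nr, nc)
  L <- design$total_length_cm
  arc <- seq(0, L, by = arc_step_cm)
  cl <- design$centerline
  x <- approx(cl$arc_cm, cl$x, xout = arc, rule = 2)$y
  y <- approx(cl$arc_cm, cl$y, xout = arc, rule = 2)$y
  # unit tangent by central differences of the interpolated centerline
  tx <- c(x[2L] - x[1L], diff(x, lag = 2L) / 2, x[length(x)] - x[length(x) - 1L])
  ty <- c(y[2L] - y[1L], diff(y, lag = 2L) / 2, y[length(y)] - y[length(y) - 1L])
  tn <- sqrt(tx^2 + ty^2)
  nx <- -ty / tn; ny <- tx / tn
  w <- as.integer(extraction_width)
  offs <- (seq_len(w) - (w + 1) / 2) * px
  xs <- outer(x, rep(1, w)) + outer(nx, offs)
  ys <- outer(y, rep(1, w)) + outer(ny, offs)
  pc <- plane_to_image(c(xs), c(ys), px, image_shape)
  r0 <- floor(pc$row); c0 <- floor(pc$col)
  if (any(r0 < 1L | r0 >= nr | c0 < 1L | c0 >= nc))
    sm_stop("geometry_error", "extraction cross-section falls outside the image")
  fr <- pc$row - r0; fc <- pc$col - c0
  i11 <- (c0 - 1L) * nr + r0
  M <- matrix(stack$intensities, nr * nc, nf)
  P <- (1 - fr) * (1 - fc) * M[i11, , drop = FALSE] +
       fr * (1 - fc) * M[i11 + 1L, , drop = FALSE] +
       (1 - fr) * fc * M[i11 + nr, , drop = FALSE] +
       fr * fc * M[i11 + nr + 1L, , drop = FALSE]
  # average the w cross-section samples of each arc position
  grp <- rep(seq_along(arc), times = w)
  prof <- rowsum(P, grp, reorder = TRUE) / w
  structure(list(matrix = prof, arc_cm = arc, arc_step_cm = arc_step_cm,
                 frame_rate = stack$frame_rate, extraction_width = w,
                 normalized = FALSE, L_cm = L),
            class = "path_profile")
}

#' @export
print.path_profile <- function(x, ...) {
  cat(sprintf("<path_profile> %d arc positions (step %.4g cm) x %d frames @ %g fps%s\n",
              nrow(x$matrix), x$arc_step_cm, ncol(x$matrix), x$frame_rate,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Filter and normalise a path profile
#'
#' The processing chain applied to each recording: (1) every frame's spatial
#' profile is low-pass filtered along the arc axis with a zero-phase
#' 3rd-order Butterworth filter at a normalised cutoff of 0.005 of the
#' spatial Nyquist frequency; (2) every (arc, frame) value is scaled by that
#' arc position's temporal mean over all frames, so the diastolic baseline
#' becomes 1 everywhere regardless of staining or illumination
#' inhomogeneity; (3) the baseline is subtracted and the residual amplified
#' to unit maximum. Being zero-phase, the filter does not move wave edges;
#' the amplification factor is irrelevant to all threshold-relative
#' measurements.
#'
#' @param profile A `path_profile`.
#' @param cutoff Spatial cutoff as a fraction of the Nyquist frequency.
#' @param order Butterworth order.
#' @return The filtered, normalised `path_profile` (temporal mean at every
#'   arc position is 1 before baseline subtraction).
#' @export
filter_and_normalize <- function(profile, cutoff = 0.005, order = 3L) {
  stopifnot(inherits(profile, "path_profile"))
  m <- profile$matrix
  if (ncol(m) < 2L)
    sm_stop("invalid_input", "need at least 2 frames to normalise")
  bf <- signal::butter(order, cutoff, type = "low")
  pad <- min(nrow(m) - 1L, ceiling(3 / cutoff))
  filt <- apply(m, 2L, zero_phase_filter, b = bf$b, a = bf$a, pad = pad)
  tm <- rowMeans(filt)
  if (any(tm <= .Machine$double.eps * 100))
    sm_stop("degenerate_signal", "zero temporal mean at %d arc position(s)", sum(tm <= 0))
  scaled <- filt / tm - 1
  amp <- max(scaled)
  if (amp <= 0) amp <- 1
  profile$matrix <- scaled / amp
  profile$normalized <- TRUE
  profile$amplification <- 1 / amp
  profile
}

#' Measure the conduction wavelength directly from a path profile
#'
#' Per frame, the wave is the maximal contiguous arc interval where the
#' signal reaches 80% of that frame's maximal wave amplitude (amplitude =
#' frame maximum minus the frame's 5th-percentile baseline, so the
#' measurement is invariant to residual drift); edges are sub-sample
#' interpolated. Only complete waves - both edges strictly inside the path
#' by at least `margin_cm` - contribute. The mean extent over at least
#' `min_waves` qualifying frames is the measured wavelength; with fewer, the
#' wavelength is reported as not measurable with the reason recorded.
#'
#' @param profile A filtered, normalised `path_profile`.
#' @param threshold Fraction of the frame's wave amplitude (default 0.8).
#' @param min_waves Minimal number of complete waves to report a mean.
#' @param margin_cm Completeness margin at the path ends; defaults to one
#'   arc step.
#' @param min_frame_amplitude Frames whose amplitude is below this fraction
#'   of the best frame's amplitude are skipped (no wave in the field).
#' @return A list of class `wl_measurement`: `measurements` tibble
#'   (`frame`, `extent_cm`, `front_cm`, `complete`), `wl_measured` (cm or
#'   NA), `n_waves`, `reason`.
#' @export
measure_wavelength <- function(profile, threshold = 0.8, min_waves = 10L,
                               margin_cm = NULL, min_frame_amplitude = 0.5) {
  stopifnot(inherits(profile, "path_profile"))
  if (!profile$normalized)
    sm_stop("invalid_input", "profile must be filtered and normalised first")
  if (is.null(margin_cm)) margin_cm <- profile$arc_step_cm
  m <- profile$matrix
  arc <- profile$arc_cm
  L <- profile$L_cm
  base_f <- apply(m, 2L, quantile, probs = 0.05, names = FALSE)
  amp_f <- apply(m, 2L, max) - base_f
  amp_ref <- max(amp_f)
  rows <- vector("list", ncol(m))
  for (f in seq_len(ncol(m))) {
    if (!is.finite(amp_f[f]) || amp_f[f] < min_frame_amplitude * amp_ref) next
    v <- m[, f]
    thr <- base_f[f] + threshold * amp_f[f]
    above <- v >= thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    # hysteresis: merge supra-threshold runs separated by dips that stay
    # above thr - 0.15 * amplitude (noise notches inside the wave plateau)
    if (length(runs) > 1L) {
      lo <- thr - 0.15 * amp_f[f]
      merged <- list(c(starts[runs[1L]], ends[runs[1L]]))
      for (k in runs[-1L]) {
        prev <- merged[[length(merged)]]
        gap <- (prev[2L] + 1L):(starts[k] - 1L)
        if (length(gap) == 0L || min(v[gap]) >= lo)
          merged[[length(merged)]] <- c(prev[1L], ends[k])
        else merged[[length(merged) + 1L]] <- c(starts[k], ends[k])
      }
      lens <- vapply(merged, function(z) z[2L] - z[1L], numeric(1))
      bestm <- merged[[which.max(lens)]]
      i1 <- bestm[1L]; i2 <- bestm[2L]
    } else {
      i1 <- starts[runs]; i2 <- ends[runs]
    }
    left <- if (i1 > 1L) {
      fr <- (thr - v[i1 - 1L]) / (v[i1] - v[i1 - 1L])
      arc[i1 - 1L] + fr * (arc[i1] - arc[i1 - 1L])
    } else arc[1L]
    right <- if (i2 < length(v)) {
      fr <- (thr - v[i2]) / (v[i2 + 1L] - v[i2])
      arc[i2] + fr * (arc[i2 + 1L] - arc[i2])
    } else arc[length(v)]
    # a wave is complete only if both edges are strictly inside the path
    # AND the signal near both path ends has returned below half amplitude
    # (otherwise a wave still entering or exiting, with a noise notch near
    # the end, would masquerade as a shorter complete wave)
    n_end <- max(2L, ceiling(max(margin_cm, 0.02) / profile$arc_step_cm))
    half <- base_f[f] + 0.5 * amp_f[f]
    ends_clear <- max(v[seq_len(n_end)]) < half &&
      max(v[(length(v) - n_end + 1L):length(v)]) < half
    complete <- (i1 > 1L) && (i2 < length(v)) &&
      left >= margin_cm && right <= L - margin_cm && ends_clear
    rows[[f]] <- data.frame(frame = f, extent_cm = right - left,
                            front_cm = right, complete = complete)
  }
  meas <- do.call(rbind, rows)
  if (is.null(meas)) meas <- data.frame(frame = integer(), extent_cm = numeric(),
                                        front_cm = numeric(), complete = logical())
  n_complete <- sum(meas$complete)
  if (n_complete >= min_waves) {
    wl <- mean(meas$extent_cm[meas$complete])
    reason <- NA_character_
  } else {
    wl <- NA_real_
    reason <- sprintf(
      "only %d complete wave(s) (< %d): wavelength exceeds or nearly exceeds the %.2f cm path",
      n_complete, min_waves, L)
  }
  structure(list(measurements = tibble::as_tibble(meas),
                 wl_measured = wl, n_waves = n_complete, reason = reason),
            class = "wl_measurement")
}

#' @export
print.wl_measurement <- function(x, ...) {
  if (is.finite(x$wl_measured))
    cat(sprintf("<wl_measurement> WL = %.3f cm over %d complete waves\n",
                x$wl_measured, x$n_waves))
  else
    cat(sprintf("<wl_measurement> not measurable: %s\n", x$reason))
  invisible(x)
}

#' Full spiral endpoint analysis of one preparation
#'
#' Runs the whole chain on one simulated or recorded preparation: profile
#' extraction, filtering/normalisation, and direct wavelength measurement
#' from the full-frame stack; APD80, travel time, and CV from the line-scan
#' pair; and the calculated wavelength CV x APD80.
#'
#' @param stack A [frame_stack()] of the spiral recording.
#' @param design The registered `spiral_design`.
#' @param linescan A `linescan_pair` from the same preparation.
#' @param extraction_width Profile cross-section width, px.
#' @param arc_step_cm Profile arc sampling step, cm.
#' @return A one-row tibble: `cv_cm_s`, `apd80_ms`, `wl_calculated`,
#'   `wl_measured` (NA when not measurable), `n_waves`.
#' @export
analyze_spiral_recording <- function(stack, design, linescan,
                                     extraction_width = 10L, arc_step_cm = 0.001) {
  prof <- extract_path_profile(stack, design, extraction_width = extraction_width,
                               arc_step_cm = arc_step_cm)
  prof <- filter_and_normalize(prof)
  wl <- measure_wavelength(prof)
  apd80 <- mean(c(linescan_apd80(linescan$trace_a, linescan$frame_rate),
                  linescan_apd80(linescan$trace_b, linescan$frame_rate)))
  tcv <- travel_time_and_cv(linescan$trace_a, linescan$trace_b,
                            linescan$separation_cm, linescan$frame_rate)
  tibble::tibble(cv_cm_s = tcv$cv_cm_s,
                 apd80_ms = apd80,
                 wl_calculated = wavelength_calculated(tcv$cv_cm_s, apd80),
                 wl_measured = wl$wl_measured,
                 n_waves = wl$n_waves)
}

#' Simulated measured-vs-calculated wavelength validation batch
#'
#' Draws `n` preparations with CV and APD80 uniform over the given ranges
#' (redrawing any whose true wavelength would exceed the path, which cannot
#' be visualised), simulates the full-frame recording and the line-scan
#' pair for each, analyses them end to end, and regresses measured on
#' calculated wavelength.
#'
#' @param n Number of preparations.
#' @param cv_range,apd80_range Uniform sampling ranges (cm/s, ms).
#' @param design Spiral design (default the calibrated 5.5 cm design).
#' @param seed Integer seed.
#' @param pixel_size,extraction_width,arc_step_cm Imaging / extraction
#'   parameters.
#' @param ... Further arguments to [spiral_sim_config()].
#' @return A list: `records` (per-preparation endpoints incl. truth),
#'   `fit` (the [wl_validation()] result).
#' @export
wl_validation_batch <- function(n = 30L, cv_range = c(15, 25),
                                apd80_range = c(150, 220),
                                design = default_design(), seed = 1L,
                                pixel_size = 40, extraction_width = 5L,
                                arc_step_cm = 0.001, ...) {
  L <- design$total_length_cm
  withr::with_seed(seed, {
    cvs <- numeric(n); apds <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        cv <- runif(1, cv_range[1L], cv_range[2L])
        apd <- runif(1, apd80_range[1L], apd80_range[2L])
        if (cv * apd / 1000 < L) break
      }
      cvs[i] <- cv; apds[i] <- apd
    }
    seeds <- sample.int(1e6, n)
  })
  region_a <- c(0.1, 0.3)
  region_b <- c(L - 0.3, L - 0.1)
  rows <- lapply(seq_len(n), function(i) {
    cfg <- spiral_sim_config(cv = cvs[i], apd80 = apds[i],
                             pixel_size = pixel_size, seed = seeds[i], ...)
    stack <- simulate_spiral_recording(design, cfg)
    ls <- simulate_linescan(design, cfg, region_a, region_b)
    res <- analyze_spiral_recording(stack, design, ls,
                                    extraction_width = extraction_width,
                                    arc_step_cm = arc_step_cm)
    res$cv_true <- cvs[i]; res$apd80_true <- apds[i]
    res
  })
  records <- dplyr::bind_rows(rows)
  list(records = records, fit = wl_validation(records))
}
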