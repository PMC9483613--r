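# Archimedean spiral micropattern geometry.
#
# The patterned conduction path is a single line of width d_l wound into a
# constant-pitch (Archimedean) spiral with an inter-line gap d_s, so the
# center-to-center pitch is d_l + d_s. The centerline is
#   r(theta) = r0 + pitch * theta / (2 * pi),
# for which the arc length has the closed form
#   s(theta) = (b / 2) * [u sqrt(u^2 + 1) + asinh(u)],  u = r / b,  b = pitch / (2 pi).
# The closed form is used for calibration and for mapping image points back
# to arc positions; the stored cumulative arc length is obtained by numerical
# (trapezoidal) integration of sqrt(r^2 + b^2) over the sampled centerline.

# Default design constants: turn count and inner radius solved (once, from the
# closed-form arc length) so that the 200/400 um line/gap design has a total
# path length of 5.5 cm and reaches 7.9 cm when one outer turn is added.
.SPIRAL_DEFAULT_N_TURNS <- 3.57634244
.SPIRAL_DEFAULT_R0 <- 1372.716859

.spiral_arc_closed_form <- function(theta, r0, b) {
  if (b == 0) return(r0 * theta)
  f <- function(u) (b / 2) * (u * sqrt(u^2 + 1) + asinh(u))
  f((r0 + b * theta) / b) - f(r0 / b)
}

#' Construct an Archimedean spiral micropattern design
#'
#' Builds the centerline of a constant-pitch spiral conduction path with line
#' width `d_l` and inter-line gap `d_s` (pitch `d_l + d_s`, center to center),
#' sampled densely enough that consecutive centerline points are at most
#' `sampling_step` micrometres apart. Cumulative arc length along the
#' centerline is computed by trapezoidal integration of the exact speed
#' `sqrt(r^2 + b^2)`.
#'
#' @param d_l Line width, um (> 0).
#' @param d_s Gap between adjacent line turns, um (>= 0).
#' @param n_turns Number of turns (> 0, non-integer allowed).
#' @param r0 Inner (starting) radius of the centerline, um (> 0).
#' @param sampling_step Maximum spacing of centerline samples, um.
#' @param pitch Radial advance per turn, um. Defaults to `d_l + d_s`; it can
#'   be overridden (e.g. 0 gives a circle of radius `r0`, useful for
#'   geometric checks).
#'
#' @return An object of class `spiral_design`: a list with the pattern
#'   parameters, the sampled centerline (`x`, `y` in um, `arc_cm` cumulative
#'   arc length in cm, `theta` in radians) and `total_length_cm`.
#' @export
#' @examples
#' d <- build_spiral(200, 400, n_turns = 2, r0 = 1000)
#' total_length(d)
build_spiral <- function(d_l, d_s, n_turns, r0,
                         sampling_step = 25, pitch = d_l + d_s) {
  check_positive(d_l, "d_l")
  check_nonnegative(d_s, "d_s")
  check_positive(n_turns, "n_turns")
  check_positive(r0, "r0")
  check_positive(sampling_step, "sampling_step")
  check_nonnegative(pitch, "pitch")
  if (sampling_step > d_l)
    sm_stop("invalid_parameter",
            "sampling_step (%g um) must not exceed the line width d_l (%g um)",
            sampling_step, d_l)
  if (pitch > 0 && d_l > pitch)
    sm_stop("geometry_error",
            "line width %g um exceeds the pitch %g um: adjacent turns of the pattern overlap",
            d_l, pitch)
  b <- pitch / (2 * pi)
  theta_end <- 2 * pi * n_turns
  r_max <- r0 + b * theta_end
  d_theta <- sampling_step / sqrt(r_max^2 + b^2)
  n_pts <- max(2L, ceiling(theta_end / d_theta) + 1L)
  theta <- seq(0, theta_end, length.out = n_pts)
  r <- r0 + b * theta
  speed <- sqrt(r^2 + b^2)
  d_th <- theta[2L] - theta[1L]
  arc_um <- c(0, cumsum((speed[-1L] + speed[-n_pts]) / 2 * d_th))
  design <- structure(list(
    d_l = d_l, d_s = d_s, pitch = pitch,
    n_turns = n_turns, r0 = r0, b = b,
    sampling_step = sampling_step,
    centerline = data.frame(
      x = r * cos(theta), y = r * sin(theta),
      theta = theta, arc_cm = arc_um / 1e4
    ),
    total_length_cm = arc_um[n_pts] / 1e4
  ), class = "spiral_design")
  validate_spiral_design(design)
  design
}

#' Validate the internal invariants of a spiral design
#'
#' Checks that the pitch equals `d_l + d_s` (unless explicitly overridden),
#' that cumulative arc length is strictly increasing and consistent with the
#' total length, and that non-adjacent turns of the patterned line do not
#' approach closer than `pitch` minus a 1 um tolerance (no self-intersection
#' of the pattern).
#'
#' @param design A `spiral_design`.
#' @param tol_um Self-intersection tolerance, um.
#' @return The design, invisibly; errors on violation.
#' @export
validate_spiral_design <- function(design, tol_um = 1) {
  if (!inherits(design, "spiral_design"))
    sm_stop("invalid_parameter", "not a spiral_design object")
  cl <- design$centerline
  arc <- cl$arc_cm
  if (any(diff(arc) <= 0))
    sm_stop("geometry_error", "cumulative arc length is not strictly increasing")
  if (abs(arc[length(arc)] - design$total_length_cm) > 1e-9)
    sm_stop("geometry_error", "total_length_cm does not match the cumulative arc length")
  # Adjacent turns are separated radially by exactly `pitch` for an
  # Archimedean spiral; verify on the sampled polyline one turn apart.
  if (design$b > 0 && design$n_turns > 1) {
    theta <- cl$theta
    i <- seq(1L, length(theta), by = 25L)
    j <- findInterval(theta[i] + 2 * pi, theta)
    keep <- j < length(theta) & j > 0L
    if (any(keep)) {
      di <- sqrt((cl$x[i[keep]] - cl$x[j[keep]])^2 + (cl$y[i[keep]] - cl$y[j[keep]])^2)
      if (any(di < design$pitch - tol_um))
        sm_stop("geometry_error",
                "non-adjacent centerline segments approach closer than the pitch")
    }
  }
  invisible(design)
}

#' The calibrated default spiral design
#'
#' Line width 200 um, gap 400 um; the turn count and inner radius are fixed
#' constants chosen so that the total conduction path is 5.5 cm and adding
#' one outer turn (`[add_turn()]`) extends it to 7.9 cm, with the whole
#' pattern fitting the ~65 mm^2 field of view of a 2x objective.
#'
#' @param sampling_step Centerline sampling step, um.
#' @return A `spiral_design`.
#' @export
#' @examples
#' total_length(default_design())  # 5.5 cm
default_design <- function(sampling_step = 25) {
  build_spiral(200, 400, n_turns = .SPIRAL_DEFAULT_N_TURNS,
               r0 = .SPIRAL_DEFAULT_R0, sampling_step = sampling_step)
}

#' Total conduction path length of a design, cm
#' @param design A `spiral_design`.
#' @return Length in cm.
#' @export
total_length <- function(design) {
  validate_spiral_design(design)
  design$total_length_cm
}

#' Add one outer turn to a spiral design
#'
#' Returns a design identical in line width, gap, pitch, and inner radius but
#' with one additional turn; the path is extended by roughly the
#' circumference of the new outermost turn.
#'
#' @param design A `spiral_design`.
#' @return A new `spiral_design` with `n_turns + 1`.
#' @export
add_turn <- function(design) {
  validate_spiral_design(design)
  build_spiral(design$d_l, design$d_s, design$n_turns + 1, design$r0,
               sampling_step = design$sampling_step, pitch = design$pitch)
}

#' Footprint of the patterned area, mm^2
#'
#' Area of an enclosure of the pattern (the centerline dilated by half the
#' line width). Two conventions are offered because "footprint" is not
#' uniquely defined for a spiral: the axis-aligned bounding box of the
#' dilated pattern (default) or the smallest origin-centred enclosing circle.
#'
#' @param design A `spiral_design`.
#' @param convention `"bounding_box"` or `"enclosing_circle"`.
#' @return Area in mm^2.
#' @export
footprint <- function(design, convention = c("bounding_box", "enclosing_circle")) {
  validate_spiral_design(design)
  convention <- match.arg(convention)
  cl <- design$centerline
  half <- design$d_l / 2
  if (convention == "bounding_box") {
    w <- (max(cl$x) - min(cl$x) + design$d_l) / 1e3
    h <- (max(cl$y) - min(cl$y) + design$d_l) / 1e3
    w * h
  } else {
    r_out <- (max(sqrt(cl$x^2 + cl$y^2)) + half) / 1e3
    pi * r_out^2
  }
}

# -- raster geometry ----------------------------------------------------------
#
# Raster convention: row-major image, origin at the top-left, the center of
# pixel (row, col) at continuous coordinates (row, col); the spiral center
# (0, 0) in the um plane maps to the image center. x increases with column,
# y with row.

#' Default image shape that holds a design with a margin
#' @noRd
default_image_shape <- function(design, pixel_size, margin_px = 4L) {
  cl <- design$centerline
  half <- design$d_l / 2
  ext <- 2 * (max(abs(c(cl$x, cl$y))) + half)
  n <- ceiling(ext / pixel_size) + 2L * margin_px
  c(n, n)
}

#' Map plane coordinates (um) to fractional image (row, col)
#' @noRd
plane_to_image <- function(x, y, pixel_size, image_shape) {
  list(row = (y + image_shape[1L] * pixel_size / 2) / pixel_size + 0.5,
       col = (x + image_shape[2L] * pixel_size / 2) / pixel_size + 0.5)
}

#' Map fractional image (row, col) to plane coordinates (um)
#' @noRd
image_to_plane <- function(row, col, pixel_size, image_shape) {
  list(x = (col - 0.5) * pixel_size - image_shape[2L] * pixel_size / 2,
       y = (row - 0.5) * pixel_size - image_shape[1L] * pixel_size / 2)
}

#' Arc position (cm) of plane points lying on or near the patterned line
#'
#' Uses the Archimedean structure: the winding number is recovered from the
#' radius, the residual angle from atan2, and the arc from the closed form.
#' Accurate to O(d_l * pitch / r) for points within the line half-width of
#' the centerline.
#' @noRd
plane_to_arc <- function(design, x, y) {
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x) %% (2 * pi)
  if (design$b == 0) {
    theta <- phi
  } else {
    theta_r <- (r - design$r0) / design$b
    k <- round((theta_r - phi) / (2 * pi))
    theta <- phi + 2 * pi * k
  }
  theta <- pmin(pmax(theta, 0), 2 * pi * design$n_turns)
  .spiral_arc_closed_form(theta, design$r0, design$b) / 1e4
}

#' Rasterize the spiral pattern to a binary mask
#'
#' A pixel is inside the mask iff its center lies within `d_l / 2` of the
#' centerline (evaluated against a centerline resampled at a quarter of the
#' pixel size, so the boundary error is well below a pixel).
#'
#' @param design A `spiral_design`.
#' @param pixel_size um per pixel.
#' @param image_shape Integer `c(rows, cols)`; defaults to the smallest
#'   square that holds the pattern with a 4-pixel margin.
#' @return A list of class `spiral_mask`: logical `mask` (rows x cols),
#'   `arc_cm` (arc position of every TRUE pixel, cm), `pixel_idx` (linear
#'   indices of TRUE pixels), `pixel_size`, `image_shape`.
#' @export
rasterize_mask <- function(design, pixel_size, image_shape = NULL) {
  validate_spiral_design(design)
  check_positive(pixel_size, "pixel_size")
  if (is.null(image_shape)) image_shape <- default_image_shape(design, pixel_size)
  image_shape <- as.integer(image_shape)
  cl <- design$centerline
  half <- design$d_l / 2
  ext_x <- max(abs(cl$x)) + half
  ext_y <- max(abs(cl$y)) + half
  if (2 * ext_x > image_shape[2L] * pixel_size || 2 * ext_y > image_shape[1L] * pixel_size)
    sm_stop("geometry_error", "pattern (%.0f x %.0f um) exceeds the image bounds",
            2 * ext_x, 2 * ext_y)
  # resample centerline at fine arc spacing for disk stamping
  step_cm <- min(pixel_size, design$d_l) / 4 / 1e4
  arc_s <- seq(0, design$total_length_cm, by = step_cm)
  xs <- approx(cl$arc_cm, cl$x, xout = arc_s)$y
  ys <- approx(cl$arc_cm, cl$y, xout = arc_s)$y
  pc <- plane_to_image(xs, ys, pixel_size, image_shape)
  rad_px <- half / pixel_size
  w <- ceiling(rad_px) + 1L
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[offs$dr^2 + offs$dc^2 <= (rad_px + 1.5)^2, ]
  nr <- image_shape[1L]; nc <- image_shape[2L]
  mask <- matrix(FALSE, nr, nc)
  r0i <- round(pc$row); c0i <- round(pc$col)
  for (k in seq_len(nrow(offs))) {
    rr <- r0i + offs$dr[k]; cc <- c0i + offs$dc[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    d2 <- (rr[ok] - pc$row[ok])^2 + (cc[ok] - pc$col[ok])^2
    hit <- d2 <= rad_px^2
    if (any(hit)) mask[cbind(rr[ok][hit], cc[ok][hit])] <- TRUE
  }
  idx <- which(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  pl <- image_to_plane(rows, cols, pixel_size, image_shape)
  structure(list(
    mask = mask,
    pixel_idx = idx,
    arc_cm = plane_to_arc(design, pl$x, pl$y),
    pixel_size = pixel_size,
    image_shape = image_shape
  ), class = "spiral_mask")
}

#' Arc position to (fractional) image pixel coordinates
#'
#' @param design A `spiral_design`.
#' @param arc_cm Arc position(s) along the path, cm, in `[0, L]`.
#' @param pixel_size um per pixel.
#' @param image_shape `c(rows, cols)`; defaults as in [rasterize_mask()].
#' @return A data.frame with fractional `row` and `col`.
#' @export
arc_to_pixel <- function(design, arc_cm, pixel_size, image_shape = NULL) {
  validate_spiral_design(design)
  if (any(arc_cm < -1e-12 | arc_cm > design$total_length_cm + 1e-12))
    sm_stop("range_error", "arc position outside [0, %.4f] cm", design$total_length_cm)
  if (is.null(image_shape)) image_shape <- default_image_shape(design, pixel_size)
  cl <- design$centerline
  x <- approx(cl$arc_cm, cl$x, xout = arc_cm, rule = 2)$y
  y <- approx(cl$arc_cm, cl$y, xout = arc_cm, rule = 2)$y
  pc <- plane_to_image(x, y, pixel_size, image_shape)
  data.frame(row = pc$row, col = pc$col)
}

#' Image pixel coordinates to arc position (cm)
#'
#' Inverse of [arc_to_pixel()] for points on (or near) the patterned line;
#' the round-trip error is below one pixel's arc equivalent.
#'
#' @inheritParams arc_to_pixel
#' @param row,col Fractional pixel coordinates.
#' @return Arc position(s), cm.
#' @export
pixel_to_arc <- function(design, row, col, pixel_size, image_shape = NULL) {
  validate_spiral_design(design)
  if (is.null(image_shape)) image_shape <- default_image_shape(design, pixel_size)
  pl <- image_to_plane(row, col, pixel_size, image_shape)
  plane_to_arc(design, pl$x, pl$y)
}

#' @export
print.spiral_design <- function(x, ...) {
  cat(sprintf(
    "<spiral_design> d_l = %g um, d_s = %g um (pitch %g um), %.4f turns, r0 = %.1f um\n",
    x$d_l, x$d_s, x$pitch, x$n_turns, x$r0))
  cat(sprintf("  path length %.4f cm, %d centerline samples (step <= %g um)\n",
              x$total_length_cm, nrow(x$centerline), x$sampling_step))
  invisible(x)
}
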