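test_that("default design hits both printed path lengths and the field of view", {
  d <- fx_design()
  expect_within(total_length(d), 5.5, 0.01 * 5.5, "default length")
  d2 <- add_turn(d)
  expect_within(total_length(d2), 7.9, 0.02 * 7.9, "added-turn length")
  expect_lte(footprint(d, "bounding_box"), 65)
})

test_that("degenerate geometries reduce to closed forms", {
  # zero pitch at fixed radius is a circle
  circ <- build_spiral(200, 400, n_turns = 1, r0 = 5000, pitch = 0)
  expect_equal(total_length(circ), 2 * pi * 0.5, tolerance = 1e-6)
  # doubling the turns strictly lengthens the path
  d1 <- build_spiral(200, 400, n_turns = 2, r0 = 1000)
  d2 <- build_spiral(200, 400, n_turns = 4, r0 = 1000)
  expect_gt(total_length(d2), total_length(d1))
})

test_that("add_turn extends by the outermost-turn circumference", {
  d <- fx_design()
  inc <- total_length(add_turn(d)) - total_length(d)
  # circumference at the mean radius of the added turn
  mean_r <- d$r0 + (d$n_turns + 0.5) * d$pitch
  expect_within(inc, 2 * pi * mean_r / 1e4, 0.01 * inc, "turn increment")
  # each successive turn is longer than the last
  inc2 <- total_length(add_turn(add_turn(d))) - total_length(add_turn(d))
  expect_gt(inc2, inc)
})

test_that("arc length is invariant under sampling refinement", {
  l1 <- total_length(default_design(sampling_step = 25))
  l2 <- total_length(default_design(sampling_step = 12.5))
  expect_lt(abs(l2 - l1) / l1, 0.001)
})

test_that("footprint conventions behave and add_turn never shrinks them", {
  d <- fx_design()
  expect_gte(footprint(d, "enclosing_circle"),
             pi * ((d$r0 + d$n_turns * d$pitch) / 1e3)^2 * 0.999)
  for (conv in c("bounding_box", "enclosing_circle"))
    expect_gte(footprint(add_turn(d), conv), footprint(d, conv))
  expect_error(footprint(d, "hexagon"))
})

test_that("invalid spiral parameters are rejected", {
  expect_error(build_spiral(-200, 400, 2, 1000), class = "invalid_parameter")
  expect_error(build_spiral(200, 400, 0, 1000), class = "invalid_parameter")
  expect_error(build_spiral(200, 400, 2, 1000, sampling_step = 300),
               class = "invalid_parameter")
})

test_that("rasterized mask area matches the analytic tube area", {
  d <- fx_design()
  m <- rasterize_mask(d, pixel_size = 20)
  analytic_px <- total_length(d) * (d$d_l / 1e4) / (20 / 1e4)^2
  expect_within(length(m$pixel_idx), analytic_px, 0.05 * analytic_px, "mask area")
  # 1 cm of 200 um line at 10 um/px covers ~ 1000 x 20 px (bent into a
  # circle so it fits one field)
  circ <- build_spiral(200, 400, n_turns = 1, r0 = 1e4 / (2 * pi),
                       sampling_step = 25, pitch = 0)
  expect_within(total_length(circ), 1, 0.01, "circumference")
  ms <- rasterize_mask(circ, pixel_size = 10)
  expect_within(length(ms$pixel_idx), 1000 * 20, 0.05 * 20000, "tube area")
})

test_that("mask rejects out-of-bounds patterns and zero-width lines", {
  d <- fx_design()
  expect_error(rasterize_mask(d, pixel_size = 40, image_shape = c(50, 50)),
               class = "geometry_error")
  expect_error(build_spiral(0, 400, 2, 1000), class = "invalid_parameter")
})

test_that("arc <-> pixel round trip is accurate to one pixel", {
  d <- fx_design()
  px <- 20
  set.seed(1)
  arcs <- c(0, total_length(d), runif(100, 0, total_length(d)))
  pc <- arc_to_pixel(d, arcs, px)
  back <- pixel_to_arc(d, pc$row, pc$col, px)
  expect_lt(max(abs(back - arcs)), px / 1e4)
  # endpoints map to the innermost / outermost centerline points
  ctr <- arc_to_pixel(d, 0, px)
  shape <- nrow(rasterize_mask(d, px)$mask)
  r_inner <- sqrt(sum((unlist(ctr) - shape / 2)^2)) * px
  expect_within(r_inner, d$r0, px, "inner endpoint radius")
  expect_error(arc_to_pixel(d, total_length(d) + 1, px), class = "range_error")
})

test_that("self-intersecting parameters are caught", {
  # a pitch far smaller than the line width forces overlap
  expect_error(build_spiral(200, 0, 3, 500, sampling_step = 20, pitch = 100),
               class = "geometry_error")
})
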