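# The heavier slice simulations are shared across tests via the fixture cache.
fx_slice <- function() fixture("slice", function()
  simulate_slice_stack(cv_long = 50, cv_trans = 25, seed = 31))
fx_slice_pp <- function() fixture("slice_pp", function() slice_preprocess(fx_slice()))

test_that("slice preprocessing handles constant, drifting, and sub-Nyquist inputs", {
  # constant stack: degenerate pixels flagged, output zeroed
  cst <- frame_stack(array(50, dim = c(8, 8, 20)), frame_rate = 1000, pixel_size = 100)
  pp <- slice_preprocess(cst)
  expect_true(all(pp$degenerate))
  expect_true(all(abs(pp$intensities) < 1e-9))
  expect_true(all(!pp$valid))
  # pure linear drift: near-zero residual after detrending
  drift <- frame_stack(array(rep(seq(100, 110, length.out = 50), each = 64),
                             dim = c(8, 8, 50)),
                       frame_rate = 1000, pixel_size = 100)
  ppd <- slice_preprocess(drift)
  expect_lt(max(abs(ppd$intensities)), 0.05)
  # low frame rates clip the temporal cutoff with a warning
  slow <- frame_stack(array(rnorm(8 * 8 * 40, 100), dim = c(8, 8, 40)),
                      frame_rate = 200, pixel_size = 100)
  expect_warning(slice_preprocess(slow), class = "cutoff_clipped")
  expect_error(slice_preprocess(frame_stack(array(1, c(4, 4, 1)), 1000, 100)),
               class = "invalid_input")
})

test_that("activation order survives preprocessing and maps are geometrically faithful", {
  pp <- fx_slice_pp()
  am <- activation_map(pp)
  truth <- fx_slice()$truth$activation_ms
  ok <- am$valid
  # monotone association between true and measured activation times
  expect_gt(cor(truth[ok], am$activation_ms[ok], method = "spearman"), 0.99)
  # point source: radially monotone along the fast axis
  ctr <- round(dim(truth) / 2)
  ray <- am$activation_ms[ctr[1], ctr[2]:(ctr[2] + 30)]
  expect_true(all(diff(ray) > -0.5))
  # planar wave: fitted gradient magnitude = 1/v within 2%
  pl <- simulate_slice_stack(cv_long = 40, cv_trans = 40, mode = "planar",
                             nx = 40L, ny = 40L, noise_sd = 0, seed = 5)
  vf <- cv_vector_field(activation_map(slice_preprocess(pl)), window = 7)
  expect_within(median(vf$speed_cm_s), 40, 0.02 * 40, "planar speed")
  # simultaneous activation everywhere: no usable gradient anywhere
  flat_map <- make_activation_map(matrix(5, 20, 20), spacing_um = 100)
  expect_error(cv_vector_field(flat_map, window = 7),
               class = "insufficient_data")
})

test_that("directional CV recovers anisotropy and orders longitudinal over transverse", {
  dcv <- directional_cv(activation_map(fx_slice_pp()), window = 7)
  expect_gte(dcv$longitudinal_cv, dcv$transverse_cv)
  ratio <- dcv$longitudinal_cv / dcv$transverse_cv
  expect_within(ratio, 2, 0.2, "anisotropy ratio")
  expect_true(min(abs(c(dcv$angle_deg, dcv$angle_deg - 180))) < 15)
  # invariance to a constant time offset
  am <- activation_map(fx_slice_pp())
  am2 <- am
  am2$activation_ms <- am2$activation_ms + 137
  dcv2 <- directional_cv(am2, window = 7)
  expect_equal(dcv2$longitudinal_cv, dcv$longitudinal_cv, tolerance = 1e-9)
})

test_that("APD90 map is uniform for a uniform template and flags sub-baseline dips", {
  pp <- fx_slice_pp()
  ap9 <- apd90_map(pp)
  truth <- fx_slice()$truth$apd90
  vals <- ap9$apd90_ms[ap9$valid]
  expect_within(median(vals), truth, 1000 / fx_slice()$frame_rate + 8, "APD90 map")
  expect_gt(sum(ap9$valid), 0.9 * sum(pp$valid))
  # inject a motion-artifact dip at one pixel
  pp2 <- pp
  nf <- dim(pp2$intensities)[3]
  tr <- pp2$intensities[50, 50, ]
  tr[round(nf * 0.8):nf] <- tr[round(nf * 0.8):nf] - 0.4
  pp2$intensities[50, 50, ] <- tr
  ap92 <- apd90_map(pp2)
  expect_true(ap92$artifact[50, 50])
  expect_false(ap92$valid[50, 50])
})

test_that("MEA corner vectors average to the monolayer CV", {
  mea <- simulate_mea(cv = 8.8, mode = "point_source", seed = 7)
  amap <- mea_activation_map(mea)
  cv <- mea_mean_cv(amap)
  expect_within(as.numeric(cv), 8.8, 0.2, "MEA mean CV")
  expect_named(attr(cv, "vectors"), c("horizontal", "vertical", "diagonal"))
  # diagonal electrode path length is sqrt(2) x the row path
  expect_equal(sqrt(2) * 7 * 450,
               sqrt((7 * 450)^2 + (7 * 450)^2))
  # instantaneous global activation: all vectors dropped, then an error
  flat <- make_activation_map(matrix(5, 8, 8), spacing_um = 450)
  expect_error(suppressWarnings(mea_mean_cv(flat)), class = "insufficient_data")
  w <- capture_warnings(tryCatch(mea_mean_cv(flat), error = function(e) NULL))
  expect_true(all(grepl("unusable", w)) && length(w) == 3L)
})
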