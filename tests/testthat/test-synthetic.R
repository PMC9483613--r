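test_that("identical seed and config reproduce recordings bit for bit", {
  d <- fx_design()
  cfg <- spiral_sim_config(cv = 25, apd80 = 200, n_frames = 30L, seed = 99)
  s1 <- simulate_spiral_recording(d, cfg)
  s2 <- simulate_spiral_recording(d, cfg)
  expect_identical(s1$intensities, s2$intensities)
  cfg2 <- spiral_sim_config(cv = 25, apd80 = 200, n_frames = 30L, seed = 100)
  s3 <- simulate_spiral_recording(d, cfg2)
  expect_false(identical(s1$intensities, s3$intensities))
})

test_that("kinematic activation times follow arc distance over cv", {
  d <- fx_design()
  cfg <- spiral_sim_config(cv = 20, apd80 = 180)
  act <- arc_activation_fun(d, cfg)
  # 1 cm of extra arc at 20 cm/s is 50 ms exactly
  expect_equal(act(2) - act(1), 50)
  expect_equal(act(0), 0)
})

test_that("a break blocks propagation distally; a bridge short-circuits it", {
  d <- fx_design()
  cfg_b <- spiral_sim_config(cv = 20, apd80 = 180,
                             defects = list(list(type = "break", arc_cm = 3)))
  act <- arc_activation_fun(d, cfg_b)
  expect_true(all(is.finite(act(c(0.5, 2.9)))))
  expect_true(all(is.infinite(act(c(3.1, 5)))))
  # bridge from 1 cm to 4 cm jumps the break
  cfg_bb <- spiral_sim_config(cv = 20, apd80 = 180,
                              defects = list(list(type = "break", arc_cm = 3),
                                             list(type = "bridge", arc_cm = c(1, 4))))
  act2 <- arc_activation_fun(d, cfg_bb)
  expect_equal(act2(4), act2(1))
  expect_equal(act2(5), act2(1) + 1 / 20 * 1000)
  # distal of a break the rendered recording carries no signal
  cfgs <- spiral_sim_config(cv = 20, apd80 = 180, n_frames = 60L, seed = 2,
                            defects = list(list(type = "break", arc_cm = 3)))
  ls <- simulate_linescan(d, cfgs, c(0.5, 0.7), c(4.0, 4.2))
  expect_error(travel_time_and_cv(ls$trace_a, ls$trace_b, 3.5, 150),
               class = "no_signal")
})

test_that("the frozen-frame supra-80% extent matches cv times the template footprint", {
  stack <- fx_stack_clean()
  d <- fx_design()
  cfg <- stack$truth$config
  prof <- extract_path_profile(stack, d, extraction_width = 5)
  # pick a frame with the wave fully inside the path
  f <- 10
  v <- prof$matrix[, f]
  b <- quantile(v, 0.05)
  thr <- b + 0.8 * (max(v) - b)
  extent <- diff(range(prof$arc_cm[v >= thr]))
  expected <- cfg$cv * stack$truth$supra80_duration_ms / 1000
  tol <- cfg$cv / cfg$frame_rate + 2 * prof$arc_step_cm
  expect_within(extent, expected, tol, "frozen-frame extent")
})

test_that("line-scan peak-time difference equals arc separation over cv", {
  d <- fx_design()
  cfg <- spiral_sim_config(cv = 30, apd80 = 180, seed = 6)
  ls <- simulate_linescan(d, cfg, c(0.45, 0.55), c(4.95, 5.05))
  expect_within(ls$truth$travel_time_ms, 4.5 / 30 * 1000, 1e-9, "true travel")
  tcv <- travel_time_and_cv(ls$trace_a, ls$trace_b, ls$separation_cm, 150)
  expect_within(tcv$travel_time_ms, 150, 1000 / 150, "measured travel")
  # overlapping regions are rejected
  expect_error(simulate_linescan(d, cfg, c(0.4, 0.6), c(0.5, 0.7)),
               class = "invalid_parameter")
  # noiseless trace APD80 equals the template value within one sample
  cfg0 <- spiral_sim_config(cv = 30, apd80 = 180, seed = 6, noise_sd = 0,
                            bleach_rate = 0)
  ls0 <- simulate_linescan(d, cfg0, c(0.45, 0.55), c(4.95, 5.05))
  expect_within(linescan_apd80(ls0$trace_a, 150, smoother = NULL), 180,
                1000 / 150, "noiseless APD80")
})

test_that("MEA simulator delays and plane-fit recovery are exact", {
  # planar wave along rows: one-pitch horizontal delay = pitch / cv
  mea <- simulate_mea(cv = 9, mode = "planar", direction_deg = 0)
  tact <- mea$truth$activation_ms
  expect_equal(tact[1, 2] - tact[1, 1], 450e-4 / 9 * 1000, tolerance = 1e-9)
  expect_equal(tact[2, 1], tact[1, 1])
  # 45 degrees: horizontal and vertical delays equal by symmetry
  mea45 <- simulate_mea(cv = 9, mode = "planar", direction_deg = 45)
  t45 <- mea45$truth$activation_ms
  expect_equal(t45[1, 2] - t45[1, 1], t45[2, 1] - t45[1, 1], tolerance = 1e-9)
  # plane-fit speed on detected times within 2% at zero noise
  vf <- cv_vector_field(mea_activation_map(mea), window = 3)
  expect_within(median(vf$speed_cm_s), 9, 0.02 * 9, "plane-fit speed")
})

test_that("patch simulator round-trips its nominal feature set", {
  tr <- simulate_patch_ap(mdp = -63.9, apa = 110, dvdt_max = 27.1,
                          apd90 = 294.6, apd_ratio = 1.34)
  ft <- extract_features(tr)
  expect_within(ft$mdp, -63.9, abs(0.01 * 63.9), "MDP")
  expect_within(ft$apa, 110, 1.1, "APA")
  expect_within(ft$dvdt_max, 27.1, 0.01 * 27.1, "dV/dt max")
  expect_within(ft$apd90, 294.6, 0.01 * 294.6, "APD90")
  expect_within(ft$apd_ratio, 1.34, 0.0134, "ratio")
  expect_error(simulate_patch_ap(apa = 0), class = "invalid_parameter")
})

test_that("background pixels carry a time-constant baseline when bleaching is off", {
  stack <- fx_stack_clean()
  msk <- rasterize_mask(fx_design(), stack$pixel_size)
  M <- matrix(stack$intensities, prod(dim(stack$intensities)[1:2]),
              dim(stack$intensities)[3])
  bg <- M[-msk$pixel_idx, ]
  means <- colMeans(bg)
  expect_lt(max(means) - min(means), 1e-9)
})
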