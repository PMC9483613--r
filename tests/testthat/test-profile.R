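test_that("profile extraction reproduces uniform images and tracks the wave kinematically", {
  d <- fx_design()
  # uniform image -> constant profile
  u <- frame_stack(array(7, dim = c(100, 100, 3)), frame_rate = 30, pixel_size = 80)
  pu <- extract_path_profile(u, d, extraction_width = 5, arc_step_cm = 0.01)
  expect_true(all(abs(pu$matrix - 7) < 1e-9))
  # noiseless wave: the supra-threshold band advances by cv * dt per frame
  stack <- fx_stack_clean()
  prof <- extract_path_profile(stack, d, extraction_width = 5)
  front_at <- function(f) {
    v <- prof$matrix[, f]
    b <- quantile(v, 0.05)
    max(prof$arc_cm[v >= b + 0.5 * (max(v) - b)])
  }
  dt_frame <- 1 / stack$frame_rate
  adv <- front_at(7) - front_at(5)
  expect_within(adv, 20 * 2 * dt_frame, 2 * prof$arc_step_cm + 0.01, "front advance")
  # extraction width is immaterial on noiseless data (wave constant across the line)
  p1 <- extract_path_profile(stack, d, extraction_width = 1, arc_step_cm = 0.004)
  expect_lt(max(abs(p1$matrix - extract_path_profile(stack, d, extraction_width = 3,
                                                     arc_step_cm = 0.004)$matrix)) /
              max(p1$matrix), 0.001)
})

test_that("filter_and_normalize scales to unit temporal mean and keeps peaks in place", {
  d <- fx_design()
  # constant-in-time profile: all ones after scaling, zeros after subtraction
  cst <- frame_stack(array(rep(100, 60 * 60 * 4), dim = c(60, 60, 4)),
                     frame_rate = 30, pixel_size = 140)
  pf <- filter_and_normalize(extract_path_profile(cst, d, extraction_width = 3,
                                                  arc_step_cm = 0.01))
  expect_true(all(abs(pf$matrix) < 1e-9))
  # normalisation invariant: temporal mean 1 before baseline subtraction
  prof <- extract_path_profile(fx_stack(), d, extraction_width = 5)
  pn <- filter_and_normalize(prof)
  reconstructed_mean <- rowMeans(pn$matrix / pn$amplification + 1)
  expect_true(all(abs(reconstructed_mean - 1) < 1e-6))
  # zero-phase: the wave's half-amplitude midpoint does not move (the argmax
  # of a flat-topped wave is ill-defined, its edges are not)
  clean <- fx_stack_clean()
  pc <- extract_path_profile(clean, d, extraction_width = 5)
  f <- 10
  mid_of <- function(v, arc) {
    b <- quantile(v, 0.05)
    half <- b + 0.5 * (max(v) - b)
    mean(range(arc[v >= half]))
  }
  before <- mid_of(pc$matrix[, f], pc$arc_cm)
  pcf <- filter_and_normalize(pc)
  after <- mid_of(pcf$matrix[, f], pcf$arc_cm)
  expect_lt(abs(after - before), 0.05)
})

test_that("the spatial low-pass attenuates high-frequency noise hard", {
  bf <- signal::butter(3, 0.005)
  n <- 2000
  x <- sin(2 * pi * 0.05 * seq_len(n))  # 10x the cutoff
  y <- spiralmap:::zero_phase_filter(x, bf$b, bf$a, pad = 600)
  att_db <- 20 * log10(sd(y[500:1500]) / sd(x[500:1500]))
  expect_lt(att_db, -20)
})

test_that("measured wavelength matches the kinematic value and respects scaling invariances", {
  d <- fx_design()
  cfg <- spiral_sim_config(cv = 20, apd80 = 150, seed = 21)
  stack <- simulate_spiral_recording(d, cfg)
  prof <- filter_and_normalize(extract_path_profile(stack, d, extraction_width = 5))
  wl <- measure_wavelength(prof)
  expect_gte(wl$n_waves, 10)
  expect_within(wl$wl_measured, 20 * stack$truth$supra80_duration_ms / 1000,
                20 / 30 + 0.1, "measured WL")
  # global intensity scaling does not move the measurement
  stack2 <- stack
  stack2$intensities <- stack2$intensities * 3.7
  prof2 <- filter_and_normalize(extract_path_profile(stack2, d, extraction_width = 5))
  wl2 <- measure_wavelength(prof2)
  expect_equal(wl2$wl_measured, wl$wl_measured, tolerance = 1e-9)
  # linear bleaching leaves the measurement essentially unchanged
  cfg_b <- spiral_sim_config(cv = 20, apd80 = 150, seed = 21, bleach_rate = 0.004)
  stack_b <- simulate_spiral_recording(d, cfg_b)
  wl_b <- measure_wavelength(filter_and_normalize(
    extract_path_profile(stack_b, d, extraction_width = 5)))
  expect_within(wl_b$wl_measured, wl$wl_measured, 0.05, "bleach invariance")
})

test_that("wavelengths beyond the path and empty profiles are reported unmeasurable", {
  d <- fx_design()
  # the fast/long case: true WL = 41 cm/s x 180.7 ms = 7.4 cm > 5.5 cm path
  cfg <- spiral_sim_config(cv = 41, apd80 = 180.7, seed = 8)
  stack <- simulate_spiral_recording(d, cfg)
  wl <- measure_wavelength(filter_and_normalize(
    extract_path_profile(stack, d, extraction_width = 5)))
  expect_true(is.na(wl$wl_measured))
  expect_match(wl$reason, "complete")
  # an all-zero profile detects nothing
  z <- structure(list(matrix = matrix(0, 200, 10), arc_cm = seq(0, 1.99, by = 0.01),
                      arc_step_cm = 0.01, frame_rate = 30, extraction_width = 1,
                      normalized = TRUE, L_cm = 1.99),
                 class = "path_profile")
  wlz <- measure_wavelength(z)
  expect_equal(wlz$n_waves, 0)
  expect_true(is.na(wlz$wl_measured))
})

test_that("degenerate profiles are refused", {
  d <- fx_design()
  dark <- frame_stack(array(0, dim = c(60, 60, 3)), frame_rate = 30, pixel_size = 140)
  pd <- extract_path_profile(dark, d, extraction_width = 3, arc_step_cm = 0.01)
  expect_error(filter_and_normalize(pd), class = "degenerate_signal")
  expect_error(measure_wavelength(pd), class = "invalid_input")
})
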