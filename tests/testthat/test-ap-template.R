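test_that("templates reproduce their nominal durations analytically and on dense grids", {
  cases <- list(
    list(tmpl = ap_template_optical(180), apd = c(`80` = 180)),
    list(tmpl = ap_template_optical(300, t_up = 5, k = 2), apd = c(`80` = 300)),
    list(tmpl = ap_template_patch(294.6, 1.34), apd = c(`90` = 294.6, `50` = 294.6 / 1.34)),
    list(tmpl = ap_template_patch(557.3, 1.1, dvdt_max = 51.1),
         apd = c(`90` = 557.3, `50` = 557.3 / 1.1))
  )
  for (cs in cases) {
    for (p in names(cs$apd)) {
      p_num <- as.numeric(p)
      expect_equal(template_apd(cs$tmpl, p_num), unname(cs$apd[p]), tolerance = 1e-7)
      # dense numerical evaluation agrees with the closed form to < 0.1 ms
      tt <- seq(-5, cs$apd[p] * 2 + 50, by = 0.005)
      v <- ap_eval(cs$tmpl, tt)
      level <- 1 - p_num / 100
      up <- tt[min(which(v >= level))]
      dn <- tt[max(which(v >= level))]
      expect_within(dn - up, unname(cs$apd[p]), 0.1, sprintf("dense APD%s", p))
    }
  }
})

test_that("template evaluation is bounded, peaks at the upstroke end, and trains repeat", {
  tmpl <- ap_template_optical(200)
  tt <- seq(-10, 600, by = 0.1)
  v <- ap_eval(tmpl, tt)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(ap_eval(tmpl, tmpl$t_up), 1)
  expect_true(all(v[tt < 0] == 0))
  tr <- ap_train(tmpl, c(100, 600, 1100), cycle_length_ms = 500, t0 = 100)
  expect_equal(tr[1L], tr[2L])
  expect_equal(tr[2L], tr[3L])
})

test_that("infeasible template parameters are rejected", {
  expect_error(ap_template_patch(300, 0.9), class = "invalid_parameter")
  expect_error(ap_template_patch(300, 1.2, apa = 0), class = "invalid_parameter")
  expect_error(ap_template(3, 2, 1), class = "invalid_parameter")  # t_half < t_up
})

test_that("restitution curves are monotone and capture follows the DI threshold", {
  m <- restitution_model(apd_max = 250, cv_max = 30, capture_threshold_di = 40)
  di <- seq(0, 1000, by = 5)
  expect_true(all(diff(restitution_apd(m, di)) >= 0))
  expect_true(all(diff(restitution_cv(m, di)) >= 0))
  scan <- simulate_s1s2(m, s2_schedule_ms = seq(600, 200, by = -10))
  # brute-force oracle: capture iff coupling - steady-state APD >= threshold
  apd_ss <- attr(scan, "apd_ss")
  expect_equal(scan$captured, scan$coupling_ms - apd_ss >= 40)
})

test_that("degenerate capture thresholds give all-false / all-true scans", {
  # threshold above the longest S2 but below the drive DI: nothing captures
  m_hi <- restitution_model(apd_max = 200, capture_threshold_di = 700)
  sc <- simulate_s1s2(m_hi, s2_schedule_ms = seq(600, 200, by = -10))
  expect_true(all(!sc$captured))
  # a drive train that cannot itself sustain capture is a protocol violation
  m_bad <- restitution_model(apd_max = 200, capture_threshold_di = 900)
  expect_error(simulate_s1s2(m_bad), class = "protocol_violation")
  m_lo <- restitution_model(apd_max = 150, alpha_apd = 0.1, capture_threshold_di = 1)
  sc2 <- simulate_s1s2(m_lo, s2_schedule_ms = seq(600, 200, by = -10))
  expect_true(all(sc2$captured))
  expect_error(simulate_s1s2(m_lo, s2_schedule_ms = c(300, 400)),
               class = "invalid_parameter")
})
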