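test_that("ERP is read off the capture scan under both conventions", {
  scan <- data.frame(coupling_ms = seq(600, 200, by = -10),
                     captured = seq(600, 200, by = -10) >= 250)
  er <- erp_from_scan(scan)
  expect_equal(er$erp_ms, 240)
  expect_true(er$reached)
  expect_equal(erp_from_scan(scan, "shortest_capture")$erp_ms, 250)
  # capture never lost
  all_cap <- data.frame(coupling_ms = seq(600, 400, by = -10), captured = TRUE)
  expect_false(erp_from_scan(all_cap)$reached)
  expect_true(is.na(erp_from_scan(all_cap)$erp_ms))
})

test_that("protocol violations in the scan are rejected", {
  expect_error(erp_from_scan(data.frame(coupling_ms = c(600, 610, 590),
                                        captured = c(TRUE, TRUE, FALSE))),
               class = "protocol_violation")
  expect_error(erp_from_scan(data.frame(coupling_ms = c(600, 590, 580),
                                        captured = c(FALSE, FALSE, FALSE))),
               class = "protocol_violation")
  expect_error(erp_from_scan(data.frame(coupling_ms = c(600, 590, 580, 570),
                                        captured = c(TRUE, FALSE, TRUE, FALSE))),
               class = "protocol_violation")
})

test_that("ERP from the simulated S1-S2 protocol lands within one decrement of truth", {
  for (thr in c(25, 38, 60)) {
    m <- restitution_model(apd_max = 210, capture_threshold_di = thr)
    scan <- simulate_s1s2(m, s2_schedule_ms = seq(600, 150, by = -10))
    er <- erp_from_scan(scan)
    expect_lte(abs(er$erp_ms - attr(scan, "erp_continuum")), 10)
  }
})

test_that("catheter CV converts span over time with proper units", {
  expect_equal(catheter_cv(50), 40)
  expect_equal(catheter_cv(20), 100)
  expect_equal(catheter_cv(100, span_mm = 10), 10)
  expect_error(catheter_cv(0), class = "invalid_parameter")
  expect_error(catheter_cv(-5), class = "invalid_parameter")
})

test_that("cohort summaries average per-record wavelengths, not products of means", {
  recs <- dplyr::bind_rows(
    endpoint_record("in_vivo", 40, 200, "ERP", "LA", "control", 500),
    endpoint_record("in_vivo", 60, 300, "ERP", "LA", "control", 500),
    endpoint_record("in_vivo", 64, 216, "ERP", "LA", "AF", 500)
  )
  s <- summarize_cohort(recs)
  wl_cell <- s[s$group == "control" & s$endpoint == "wl_cm", ]
  # mean of products: (40*0.2 + 60*0.3) / 2 = 13, not 50 * 0.25 = 12.5
  expect_equal(wl_cell$mean, 13)
  expect_equal(wl_cell$n, 2L)
  # single-record cells carry NA SEM
  af_cv <- s[s$group == "AF" & s$endpoint == "cv_cm_s", ]
  expect_true(is.na(af_cv$sem))
  expect_equal(af_cv$mean, 64)
  # permutation invariance
  s2 <- summarize_cohort(recs[c(3, 1, 2), ])
  expect_equal(s, s2)
  expect_error(summarize_cohort(recs[0, ]), class = "invalid_input")
})

test_that("endpoint records enforce their vocabulary and compute WL", {
  r <- endpoint_record("spiral", 20, 180, "APD80")
  expect_equal(r$wl_cm, 3.6)
  expect_error(endpoint_record("balloon", 20, 180, "APD80"))
  expect_error(endpoint_record("spiral", -2, 180, "APD80"),
               class = "invalid_parameter")
})
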