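test_that("feature extraction recovers nominal parameters and analytic shapes", {
  # triangle AP: linear repolarisation gives APD90/APD50 = 9/5 exactly
  fs <- 5000
  dt <- 1000 / fs
  seg <- function(from, to, dur) seq(from, to, length.out = round(dur / dt))
  v <- c(rep(-80, round(300 / dt)), seg(-80, 20, 2), seg(20, -80, 300),
         rep(-80, round(300 / dt)))
  ft <- extract_features(v, sample_rate = fs)
  expect_within(ft$apd_ratio, 1.8, 0.02, "triangle ratio")
  expect_within(ft$apa, 100, 1, "triangle APA")
  expect_within(ft$dvdt_max, 100 / 2, 6, "triangle upstroke")
  # a flat trace has no signal
  expect_error(extract_features(rep(-70, 5000), sample_rate = 5000),
               class = "no_signal")
  # sub-kHz sampling is refused
  expect_error(extract_features(v[seq(1, length(v), by = 10)], sample_rate = 500),
               class = "invalid_parameter")
})

test_that("feature extraction is invariant to time origin and resampling", {
  tr <- simulate_patch_ap(seed = 3)
  ft <- extract_features(tr)
  shifted <- tr
  shifted$time_ms <- shifted$time_ms + 250
  fts <- extract_features(shifted)
  expect_equal(fts$apd90, ft$apd90, tolerance = 0.01)
  half <- tr[seq(1, nrow(tr), by = 2), ]  # 5 kHz -> 2.5 kHz
  fth <- extract_features(half)
  expect_lt(abs(fth$apd90 - ft$apd90) / ft$apd90, 0.01)
  expect_lt(abs(fth$dvdt_max - ft$dvdt_max) / ft$dvdt_max, 0.05)
})

test_that("the three canonical examples classify identically under both rule sets", {
  cases <- list(
    list(f = ap_features(-45, 90, 3, 250, 1.3), label = "nodal"),
    list(f = ap_features(-70, 110, 51.1, 557.3, 1.1), label = "ventricular"),
    list(f = ap_features(-63.9, 110, 27.1, 294.6, 1.34), label = "atrial")
  )
  for (cs in cases) for (rs in c("text", "caption"))
    expect_equal(classify(cs$f, rs)$label, cs$label,
                 label = sprintf("%s under %s rules", cs$label, rs))
})

test_that("rule conflicts and the MDP gap stay unclassified with an explanation", {
  # both working-myocyte disjunctions fire: APD90 450 ms with ratio 1.3
  confl <- classify(ap_features(-65, 110, 20, 450, 1.3), "text")
  expect_equal(confl$label, "unclassified")
  expect_true(any(grepl("conflict", confl$rule_trace)))
  # the -55..-50 mV MDP gap matches no text rule
  gap <- classify(ap_features(-52, 110, 20, 250, 1.3), "text")
  expect_equal(gap$label, "unclassified")
  expect_true(any(grepl("gap", gap$rule_trace)))
  # caption rules: MDP -58 working myocyte fails the -60 gate
  gap2 <- classify(ap_features(-58, 110, 20, 250, 1.3), "caption")
  expect_equal(gap2$label, "unclassified")
  # classification is total and deterministic over a parameter sweep
  set.seed(2)
  for (i in 1:50) {
    f <- ap_features(runif(1, -90, -30), runif(1, 60, 140), runif(1, 0.5, 80),
                     runif(1, 100, 900), runif(1, 1.01, 2))
    l1 <- classify(f)$label
    expect_true(l1 %in% c("nodal", "atrial", "ventricular", "unclassified"))
    expect_identical(classify(f)$label, l1)
  }
})

test_that("population proportions sum to one and recover generator mixing fractions", {
  expect_equal(population_summary(rep("atrial", 4))$fraction,
               c(0, 1, 0, 0))
  ps <- population_summary(c(rep("nodal", 3), rep("atrial", 7)))
  expect_equal(ps$fraction[ps$label == "nodal"], 0.3)
  expect_error(population_summary(character(0)), class = "invalid_input")
  pop <- simulate_patch_population(n = 40, seed = 14)
  labels <- vapply(pop$traces, function(tr) classify(extract_features(tr))$label,
                   character(1))
  expect_equal(labels, pop$cells$true_class)
  ps2 <- population_summary(labels)
  expect_equal(sum(ps2$fraction), 1)
  truth <- table(factor(pop$cells$true_class,
                        levels = c("nodal", "atrial", "ventricular", "unclassified")))
  expect_equal(ps2$n, as.integer(truth))
})
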