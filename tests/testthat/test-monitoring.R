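test_that("the reference distribution is a normalised histogram of the baseline", {
  # degenerate stream: all mass in one bin
  r <- build_reference(score_stream(rep(80, 700)), baseline_duration = 600)
  expect_equal(sum(r$probabilities), 1, tolerance = 1e-9)
  expect_equal(max(r$probabilities), 1)
  expect_equal(r$n_samples, 600)
  # uniform bin occupancy normalises to equal probabilities
  sc <- rep(seq(2.5, 97.5, by = 5), times = 40)
  r2 <- build_reference(score_stream(sc), baseline_duration = 600, bins = 20)
  expect_equal(unname(r2$probabilities), rep(0.05, 20), tolerance = 1e-12)
  expect_equal(sum(r2$probabilities), 1, tolerance = 1e-9)
})

test_that("the reference refuses to build before enough baseline exists", {
  expect_error(build_reference(score_stream(numeric(0))), class = "lw_not_ready")
  expect_error(build_reference(score_stream(rep(50, 30))),  # 30 s < baseline
               class = "lw_not_ready")
  expect_error(build_reference(score_stream(rep(50, 700)), min_samples = 1e5),
               class = "lw_not_ready")
})

test_that("window comparison alarms only on deterioration", {
  ref <- build_reference(score_stream(rep(90, 700)), baseline_duration = 600)
  same <- score_stream(rep(90, 300))
  wc <- window_compare(ref, same, thin_s = 0)
  expect_equal(wc$statistic, 0)
  expect_false(wc$is_shifted)
  worse <- score_stream(rep(40, 300))
  wc2 <- window_compare(ref, worse, thin_s = 0)
  expect_equal(wc2$statistic, 1)
  expect_true(wc2$is_shifted)
  # an improving driver must never raise an impairment alarm
  ref_low <- build_reference(score_stream(rep(40, 700)), baseline_duration = 600)
  wc3 <- window_compare(ref_low, score_stream(rep(90, 300)), thin_s = 0)
  expect_equal(wc3$statistic, 1)
  expect_false(wc3$is_shifted)
  expect_error(window_compare(ref, score_stream(numeric(0))),
               class = "lw_invalid_input")
})

test_that("shift detection is one-sided under random permutations upward", {
  set.seed(12)
  base <- pmin(100, pmax(0, rnorm(700, 60, 8)))
  ref <- build_reference(score_stream(base), baseline_duration = 600)
  for (rep in 1:10) {
    win <- score_stream(pmin(100, rnorm(300, 85, 8)))
    expect_false(window_compare(ref, win, thin_s = 0)$is_shifted)
  }
})

test_that("trend test combines slope magnitude with Mann-Kendall confirmation", {
  tt <- trend_test(score_stream(80 - 2 * (0:299) / 60), thin_s = 0)
  expect_equal(tt$slope, -2, tolerance = 1e-9)
  expect_true(tt$is_declining)
  flat <- trend_test(score_stream(rep(70, 300)), thin_s = 0)
  expect_equal(flat$slope, 0)
  expect_false(flat$is_declining)
  up <- trend_test(score_stream(50 + 2 * (0:299) / 60), thin_s = 0)
  expect_gt(up$slope, 0)
  expect_false(up$is_declining)
  # a steep slope that is not monotone enough for Mann-Kendall stays silent
  set.seed(5)
  noisy <- score_stream(60 + c(rnorm(150, 5, 30), rnorm(150, -5, 30)))
  ttn <- trend_test(noisy, thin_s = 0, alpha = 1e-12)
  expect_false(ttn$is_declining)
  expect_error(trend_test(score_stream(rep(1, 5)), min_points = 30),
               class = "lw_invalid_input")
})

test_that("detect_impairment is deterministic and silent on short or flat streams", {
  expect_warning(a0 <- detect_impairment(score_stream(rep(70, 100)), lw_cfg))
  expect_equal(nrow(a0), 0)
  set.seed(9)
  scores <- pmin(100, pmax(0, c(rnorm(1300, 70, 8), rnorm(700, 30, 8))))
  stream <- score_stream(scores)
  a1 <- detect_impairment(stream, lw_cfg)
  a2 <- detect_impairment(stream, lw_cfg)
  expect_identical(a1, a2)
  expect_gt(nrow(a1), 0)
  expect_true(all(a1$kind %in% c("distribution_shift", "negative_trend")))
  # the collapse at t = 1300 s must be flagged only after it happens
  expect_true(all(a1$t >= 1300))
})

test_that("alarms of one kind respect the refractory period", {
  set.seed(10)
  scores <- pmin(100, pmax(0, c(rnorm(1300, 70, 8), rnorm(1700, 25, 8))))
  alarms <- detect_impairment(score_stream(scores), lw_cfg)
  for (k in unique(alarms$kind)) {
    ts <- alarms$t[alarms$kind == k]
    if (length(ts) > 1)
      expect_true(all(diff(ts) >= lw_cfg$monitoring$refractory_s))
  }
})

test_that("rebuilding the reference after appending records keeps mass in [0, 100]", {
  set.seed(11)
  s1 <- score_stream(pmin(100, pmax(0, rnorm(700, 65, 10))))
  r1 <- build_reference(s1)
  s2 <- rbind(s1, data.frame(t = 700:1400, score = runif(701, 0, 100)))
  r2 <- build_reference(s2, baseline_duration = 1200)
  for (r in list(r1, r2)) {
    expect_equal(sum(r$probabilities), 1, tolerance = 1e-9)
    expect_true(all(r$probabilities >= 0))
    expect_equal(r$bin_edges[1], 0)
    expect_equal(r$bin_edges[length(r$bin_edges)], 100)
  }
})
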