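test_that("the default rule matrix encodes convergence-is-safe and is point-symmetric", {
  m <- default_rule_matrix()
  # centred and not drifting is the safest state
  expect_equal(m$grid["C", "C"], "S+")
  # far right and still drifting strongly right diverges off track
  expect_equal(m$grid["Dx+", "Dx+"], "Us+")
  # offset right with a mild leftward drift converges back to centre
  expect_equal(m$grid["Dx", "Sx"], "S+")
  # mirroring both inputs leaves the judgment unchanged
  for (i in 1:5) for (j in 1:5)
    expect_equal(m$grid[i, j], m$grid[6 - i, 6 - j])
})

test_that("rule matrices are validated for shape and label legality", {
  g <- matrix("S", 5, 5)
  expect_s3_class(rule_matrix(g, in_labels, in_labels), "rule_matrix")
  g_bad <- g; g_bad[3, 3] <- "WAT"
  expect_error(rule_matrix(g_bad, in_labels, in_labels),
               class = "lw_invalid_config")
  expect_error(rule_matrix(matrix("S", 4, 5), in_labels, in_labels),
               class = "lw_invalid_config")
})

test_that("Mamdani activation takes min over antecedents and max per conclusion", {
  m <- lw_cfg$rules
  one_hot <- function(lab) {
    v <- stats::setNames(numeric(5), in_labels); v[lab] <- 1; v
  }
  expect_equal(infer(one_hot("C"), one_hot("C"), m),
               c("Us+" = 0, "Us" = 0, "NSS" = 0, "S" = 0, "S+" = 1))
  # two rules fire: (C,C)->S+ at 0.5 and (Dx,C)->NSS at 0.5
  act_lp <- stats::setNames(c(0, 0, 0.5, 0.5, 0), in_labels)
  expect_equal(infer(act_lp, one_hot("C"), m),
               c("Us+" = 0, "Us" = 0, "NSS" = 0.5, "S" = 0, "S+" = 0.5))
  zero <- stats::setNames(numeric(5), in_labels)
  expect_equal(infer(zero, zero, m), stats::setNames(numeric(5), out_labels))
  bad <- stats::setNames(numeric(5), rev(in_labels))
  expect_error(infer(bad, one_hot("C"), m), class = "lw_invalid_config")
})

test_that("at most four rules fire for crisp inputs under Ruspini partitions", {
  set.seed(7)
  for (rep in 1:50) {
    rec <- judge(list(t = 0, lp_m = runif(1, -2.5, 2.5),
                      lp_prime_cmps = runif(1, -25, 25)), lw_cfg)
    expect_lte(nrow(rec$fired_rules), 4)
    expect_true(all(rec$fired_rules$strength > 0 & rec$fired_rules$strength <= 1))
  }
})

test_that("centre-of-areas defuzzification matches symmetry and the numeric oracle", {
  outp <- lw_cfg$partitions$judgment
  act <- function(...) stats::setNames(c(...), out_labels)
  # symmetric single triangle centred at 50
  expect_equal(defuzzify_coa(outp, act(0, 0, 1, 0, 0)), 50, tolerance = 1e-6)
  # symmetric envelopes about 50 for any common height
  for (h in c(0.2, 0.6, 1))
    expect_equal(defuzzify_coa(outp, act(h, 0, 0, 0, h)), 50, tolerance = 1e-6)
  # the shouldered extreme set, against the independent integration oracle
  sp <- act(0, 0, 0, 0, 1)
  expect_equal(defuzzify_coa(outp, sp), oracle_coa(sp), tolerance = 1e-3)
  expect_equal(defuzzify_coa(outp, sp), 275 / 3, tolerance = 5e-3)
  expect_error(defuzzify_coa(outp, act(0, 0, 0, 0, 0)),
               class = "lw_no_rule_fired")
  expect_error(defuzzify_coa(outp, sp, resolution = 50),
               class = "lw_invalid_config")
})

test_that("judge composes the pipeline and honours mirror symmetry", {
  r0 <- judge(list(t = 0, lp_m = 0, lp_prime_cmps = 0), lw_cfg)
  expect_equal(r0$score, 275 / 3, tolerance = 5e-3)
  expect_equal(r0$fired_rules$output_label, "S+")
  # worst corner: full Us+ activation gives the grid minimum
  rw <- judge(list(t = 0, lp_m = 2, lp_prime_cmps = 20), lw_cfg)
  expect_equal(rw$score, 100 - 275 / 3, tolerance = 5e-3)
  set.seed(21)
  for (rep in 1:25) {
    lp <- runif(1, -2, 2); lpp <- runif(1, -20, 20)
    a <- judge(list(t = 0, lp_m = lp, lp_prime_cmps = lpp), lw_cfg)$score
    b <- judge(list(t = 0, lp_m = -lp, lp_prime_cmps = -lpp), lw_cfg)$score
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("judge_trace agrees with per-sample judge and reports fired rules", {
  set.seed(33)
  tr <- data.frame(t = 0:19, lp_m = runif(20, -2.2, 2.2),
                   lp_prime_cmps = runif(20, -22, 22))
  bulk <- judge_trace(tr, lw_cfg, include_rules = TRUE)
  single <- vapply(seq_len(nrow(tr)), function(i)
    judge(as.list(tr[i, ]), lw_cfg)$score, numeric(1))
  expect_equal(bulk$score, single, tolerance = 1e-12)
  expect_true(all(grepl(">", bulk$fired_rules)))
  expect_error(judge_trace(data.frame(t = 1, lp_m = 0), lw_cfg),
               class = "lw_invalid_input")
})

test_that("the drift sign-flip option mirrors the drift axis only", {
  flipped <- unclass(lw_cfg)
  flipped$lp_prime_sign <- -1
  flipped <- validate_config(flipped)
  s_plus <- judge(list(t = 0, lp_m = 1, lp_prime_cmps = 10), flipped)$score
  s_ref <- judge(list(t = 0, lp_m = 1, lp_prime_cmps = -10), lw_cfg)$score
  expect_equal(s_plus, s_ref, tolerance = 1e-12)
})

test_that("the Dx row grades drift monotonically at pure drift labels and past the corrective optimum", {
  # at lp = 1 m (pure Dx), the five pure drift labels give non-increasing
  # judgments: strong correction and mild correction are both very safe,
  # then quality falls as the drift turns divergent
  pure <- vapply(c(-20, -10, 0, 10, 20), function(lpp)
    judge(list(t = 0, lp_m = 1, lp_prime_cmps = lpp), lw_cfg)$score, numeric(1))
  expect_true(all(diff(pure) <= 1e-9))
  expect_equal(pure[1], pure[2], tolerance = 1e-9)
  # on the dense axis the decline is strict from the corrective optimum
  # (lp' = -10) onward; between -20 and -10 the centre-of-areas centroid of
  # the partially clipped S+ shoulder ripples by at most ~1.4 score units
  lpp <- (-100:200) / 10
  s <- judge_trace(data.frame(t = seq_along(lpp), lp_m = 1,
                              lp_prime_cmps = lpp), lw_cfg)$score
  expect_true(all(diff(s) <= 1e-9))
  lpp_all <- (-200:200) / 10
  s_all <- judge_trace(data.frame(t = seq_along(lpp_all), lp_m = 1,
                                  lp_prime_cmps = lpp_all), lw_cfg)$score
  expect_lt(max(s_all) - max(s_all[lpp_all >= -10]), 1e-9)
  expect_lt(max(diff(s_all)), 1.5)
})
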