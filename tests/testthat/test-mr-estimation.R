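# Published inputs: IL-6 exposure rs2228145 (0.17, 0.012), rs12048091
# (0.09, 0.016); CHD outcome (-0.05, 0.010) and (0.02, 0.013).

test_that("Wald ratio reproduces the CHD positive control", {
  pairs <- chd_pairs()
  est <- wald_ratio(pairs[pairs$rsid == "rs2228145", ])
  expect_equal(est$beta, -0.05 / 0.17)
  expect_equal(est$se, 0.010 / 0.17)
  expect_equal(est$odds_ratio, exp(-0.05 / 0.17))
  expect_equal(round(est$odds_ratio, 2), 0.75)
  expect_equal(round(est$or_ci_low, 2), 0.66)
  expect_equal(round(est$or_ci_high, 2), 0.84)
  expect_lt(est$pvalue, 0.001)
})

test_that("second-order delta SE adds the exposure term and dominates", {
  pair <- make_pair(0.17, 0.012, -0.05, 0.010)
  e1 <- wald_ratio(pair, "first_order")
  e2 <- wald_ratio(pair, "second_order")
  # independent arithmetic: sqrt(0.010^2/0.17^2 + 0.05^2*0.012^2/0.17^4)
  expect_equal(e2$se, sqrt(1e-4 / 0.0289 + 2.5e-3 * 1.44e-4 / 0.17^4))
  expect_equal(round(e2$se, 4), 0.0624)
  expect_gt(e2$se, e1$se)
  expect_equal(e2$beta, e1$beta)
})

test_that("null outcome and degenerate inputs behave as defined", {
  expect_equal(wald_ratio(make_pair(0.17, 0.012, 0, 0.01))$odds_ratio, 1)
  expect_error(wald_ratio(make_pair(0, 0.012, 0.05, 0.01)), "zero")
  q <- make_pair(0.17, 0.012, -0.09, 0.002, outcome_type = "quantitative")
  est <- wald_ratio(q)
  expect_true(is.na(est$odds_ratio))          # no odds fields for SD scale
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  pairs <- chd_pairs()
  est <- ivw(pairs)
  # explicit summation oracle with w_j = b_xj^2 / se_yj^2
  r <- c(-0.05 / 0.17, 0.02 / 0.09)
  w <- c(0.17^2 / 0.010^2, 0.09^2 / 0.013^2)
  expect_equal(est$beta, sum(w * r) / sum(w))
  expect_equal(est$se, 1 / sqrt(sum(w)))
  expect_equal(round(est$beta, 3), -0.221)
  expect_equal(round(est$se, 4), 0.0545)
  expect_equal(est$n_snps, 2)
})

test_that("IVW reduces to the Wald ratio for one pair and halves variance
           for duplicated pairs", {
  pair <- make_pair(0.17, 0.012, -0.05, 0.010)
  w1 <- wald_ratio(pair, "first_order")
  i1 <- ivw(pair)
  expect_equal(i1$beta, w1$beta)
  expect_equal(i1$se, w1$se)
  i2 <- ivw(rbind(pair, pair))
  expect_equal(i2$beta, w1$beta)
  expect_equal(i2$se, w1$se / sqrt(2))
  expect_error(ivw(pair[0, ]), "at least one")
})

test_that("F statistics equal squared association z-scores", {
  f <- f_statistic(il6_associations())
  expect_equal(unname(f["rs2228145"]), (0.17 / 0.012)^2)
  expect_equal(round(unname(f["rs2228145"]), 1), 200.7)
  expect_equal(unname(f["rs12048091"]), (0.09 / 0.016)^2)
  expect_equal(round(unname(f["rs12048091"]), 1), 31.6)
  m <- quant_meta()
  null <- association_table("rs0", "C", "A", 0.5, 0, 0.01, 1, m)
  expect_equal(unname(f_statistic(null)), 0)
})

test_that("biomarker effects are scaled to SD of exposure without odds fields", {
  il6 <- il6_associations()
  crp <- outcome_associations("CRP")
  est <- scaled_biomarker_effect(il6[1, ], crp[1, ])
  expect_equal(est$beta, -0.09 / 0.17)
  expect_equal(round(est$beta, 2), -0.53)
  expect_equal(round(est$ci_low, 2), -0.55)
  expect_equal(round(est$ci_high, 2), -0.51)
  expect_true(is.na(est$odds_ratio))
  fib <- outcome_associations("fibrinogen")
  expect_equal(round(scaled_biomarker_effect(il6[1, ], fib[1, ])$beta, 2),
               -0.06)
  expect_equal(round(scaled_biomarker_effect(il6[2, ], fib[2, ])$beta, 2),
               -0.11)
  ra <- outcome_associations("RA")
  expect_error(scaled_biomarker_effect(il6[1, ], ra[1, ]), "quantitative")
})

test_that("estimator properties hold across random inputs", {
  set.seed(42)
  for (i in 1:50) {
    bx <- runif(1, 0.05, 0.5) * sample(c(-1, 1), 1)
    sx <- runif(1, 0.005, 0.05)
    by <- rnorm(1, 0, 0.2)
    sy <- runif(1, 0.005, 0.1)
    pair <- make_pair(bx, sx, by, sy)
    est <- wald_ratio(pair)
    # scale invariance: scaling the exposure by c scales the ratio by 1/c
    cc <- runif(1, 0.1, 10)
    scaled <- wald_ratio(make_pair(cc * bx, cc * sx, by, sy))
    expect_equal(scaled$beta, est$beta / cc)
    expect_equal(scaled$beta / scaled$se, est$beta / est$se)
    # sign flip of exactly one side flips the ratio
    expect_equal(wald_ratio(make_pair(-bx, sx, by, sy))$beta, -est$beta)
    expect_equal(wald_ratio(make_pair(bx, sx, -by, sy))$beta, -est$beta)
    # second order never undercuts first order
    expect_gte(wald_ratio(pair, "second_order")$se, est$se)
    # p equals the chi-square(1) tail of z^2
    expect_equal(est$pvalue,
                 pchisq((est$beta / est$se)^2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})
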