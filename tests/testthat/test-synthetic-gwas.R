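# Moderate cohort sizes keep these checks fast; the full-size parameter
# recovery experiments live in the acceptance suite.

test_that("genotype frequencies and correlations match the configuration", {
  cfg <- simulation_config(10000, 1000, table1_variants(),
                           pairwise_r = 0, seed = 5)
  set.seed(5)
  g <- simulate_genotypes(cfg, 10000)
  expect_true(all(g %in% 0:2))
  expect_equal(unname(colMeans(g) / 2), c(0.38, 0.82), tolerance = 0.02)
  expect_lt(abs(cor(g)[1, 2]), 0.05)          # independent variants

  half <- simulation_config(10000, 1000,
                            data.frame(rsid = "v", eaf = 0.5, beta = 0.1),
                            seed = 5)
  set.seed(5)
  expect_equal(mean(simulate_genotypes(half, 10000)), 1.0, tolerance = 0.03)
})

test_that("the copula calibration hits the target dosage correlation", {
  cfg <- simulation_config(50000, 1000, table1_variants(),
                           pairwise_r = 0.33, seed = 9)
  set.seed(9)
  g <- simulate_genotypes(cfg, 50000)
  expect_equal(cor(g)[1, 2], 0.33, tolerance = 0.02)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulation_config(1000, 1000, table1_variants(),
                                 pairwise_r = bad), "positive semi-definite")
})

test_that("traits follow the configured generative model", {
  cfg <- simulation_config(50000, 1000, table1_variants(),
                           gamma = 0, intercept = qlogis(0.08), seed = 3)
  set.seed(3)
  g <- simulate_genotypes(cfg, 50000)
  tr <- simulate_traits(g, cfg)
  expect_equal(var(tr$exposure), 1, tolerance = 0.03)
  expect_lt(abs(mean(tr$outcome) - 0.08), 0.005)  # binomial sampling error
  # null outcome model: per-variant outcome log-odds compatible with zero
  scan <- summary_scan(g, tr$outcome, "binary", cfg$variants)
  expect_true(all(abs(scan$beta) < 3 * scan$se))
  # a genetic variance at or above 1 is rejected
  big <- data.frame(rsid = "v", eaf = 0.5, beta = 1.5)
  expect_error(simulate_traits(g[, 1, drop = FALSE],
                               simulation_config(1000, 1000, big)),
               "below 1")
})

test_that("the exposure scan recovers per-allele effects within 2 SE", {
  cfg <- simulation_config(50000, 1000, table1_variants(), seed = 17)
  set.seed(17)
  g <- simulate_genotypes(cfg, 50000)
  tr <- simulate_traits(g, cfg)
  scan <- summary_scan(g, tr$exposure, "quantitative", cfg$variants,
                       trait_label = "exposure")
  expect_equal(scan$trait_type, rep("quantitative", 2))
  expect_true(abs(scan$beta[1] - 0.17) < 2 * scan$se[1])
  expect_true(abs(scan$beta[2] - 0.09) < 2 * scan$se[2])
  # scan SEs agree with regression theory 1/sqrt(2p(1-p)n)
  expect_equal(scan$se,
               1 / sqrt(2 * scan$eaf * (1 - scan$eaf) * 50000),
               tolerance = 0.05)
})

test_that("the binary scan is consistent with the instrument-level
           expectation outcome_beta ~ gamma * exposure_beta", {
  cfg <- simulation_config(1000, 100000, table1_variants(), gamma = 0.6,
                           intercept = -2.5, seed = 23)
  set.seed(23)
  g <- simulate_genotypes(cfg, 100000)
  tr <- simulate_traits(g, cfg)
  scan <- summary_scan(g, tr$outcome, "binary", cfg$variants)
  expect_equal(scan$trait_type, rep("binary", 2))
  expect_equal(scan$n_cases + scan$n_controls, rep(100000, 2))
  expect_true(abs(scan$beta[1] - 0.6 * 0.17) < 2 * scan$se[1])
  expect_true(abs(scan$beta[2] - 0.6 * 0.09) < 2 * scan$se[2])
})

test_that("monomorphic variants are flagged and skipped", {
  g <- cbind(v1 = rep(1L, 100), v2 = rbinom(100, 2, 0.5))
  v <- data.frame(rsid = c("v1", "v2"), eaf = c(0.5, 0.5),
                  beta = c(0, 0), effect_allele = c("C", "A"),
                  other_allele = c("A", "G"))
  expect_message(scan <- summary_scan(g, rnorm(100), "quantitative", v),
                 "monomorphic")
  expect_equal(scan$rsid, "v2")
})

test_that("a fixed seed makes the whole study reproducible, including
           written files", {
  cfg <- simulation_config(2000, 2000, table1_variants(), gamma = 0.6,
                           pairwise_r = 0.33, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_study(cfg, dir = d1)
  s2 <- generate_study(cfg, dir = d2)
  expect_equal(s1$exposure_assocs, s2$exposure_assocs)
  expect_equal(s1$outcome_assocs, s2$outcome_assocs)
  for (f in c("exposure.tsv", "outcome.tsv", "ld.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # exposure and outcome scans come from disjoint cohorts: under a fixed
  # seed, changing only the outcome cohort size leaves the exposure scan
  # untouched
  cfg2 <- simulation_config(2000, 3000, table1_variants(), gamma = 0.6,
                            pairwise_r = 0.33, seed = 77)
  s3 <- generate_study(cfg2)
  expect_equal(s1$exposure_assocs, s3$exposure_assocs)
  expect_false(isTRUE(all.equal(s1$outcome_assocs$beta,
                                s3$outcome_assocs$beta)))
})

test_that("written study files feed straight back into the pipeline readers", {
  cfg <- simulation_config(3000, 3000, table1_variants(), gamma = 0.6,
                           seed = 13)
  d <- withr::local_tempdir()
  st <- generate_study(cfg, dir = d)
  m <- study_meta("sim", "exposure", "quantitative", n = 3000)
  back <- read_associations(file.path(d, "exposure.tsv"), m)
  expect_equal(back$beta, st$exposure_assocs$beta)
  ld <- read_ld(file.path(d, "ld.tsv"))
  expect_equal(ld$r2["rs2228145", "rs12048091"],
               st$ld$r2["rs2228145", "rs12048091"])
})

test_that("instrument strength scales linearly with cohort size", {
  f_at <- function(n, seed) {
    cfg <- simulation_config(n, 100, table1_variants(), seed = seed)
    set.seed(seed)
    g <- simulate_genotypes(cfg, n)
    tr <- simulate_traits(g, cfg)
    scan <- summary_scan(g, tr$exposure, "quantitative", cfg$variants)
    unname(f_statistic(scan)["rs2228145"])
  }
  f1 <- mean(vapply(1:5, function(i) f_at(10000, 100 + i), 0))
  f2 <- mean(vapply(1:5, function(i) f_at(20000, 200 + i), 0))
  expect_equal(f2 / f1, 2, tolerance = 0.35)
})
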