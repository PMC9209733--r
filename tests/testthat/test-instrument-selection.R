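test_that("palindrome detection follows the allele-pair definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("C", "A"))  # the retained missense variant
  expect_false(is_palindromic("A", "G"))
  expect_error(is_palindromic("N", "A"), "non-ACGT")
})

test_that("selection applies p, MAF, palindrome and LD filters with a full log", {
  m <- quant_meta("IL-6", 30000)
  cand <- association_table(
    rsid = c("rs2228145", "rs12048091", "rs10752641"),
    effect_allele = c("C", "A", "A"), other_allele = c("A", "G", "T"),
    eaf = c(0.38, 0.82, 0.30),
    beta = c(0.17, 0.09, 0.08), se = c(0.012, 0.016, 0.014),
    pvalue = c(3.34e-45, 3.95e-8, 1.1e-8), meta = m)
  ld <- read_ld(targetmr_example("ld_synthetic.tsv"))
  sel <- select_instruments(cand, selection_criteria(), ld)
  expect_setequal(sel$assocs$rsid, c("rs2228145", "rs12048091"))
  log <- sel$selection_log
  expect_equal(nrow(log), 3)                  # one decision per candidate
  expect_equal(log$reason[log$rsid == "rs10752641"], "palindromic")
  expect_true(all(log$retained[log$rsid != "rs10752641"]))
  expect_equal(sel$ld$r2["rs2228145", "rs12048091"], 0.11)
})

test_that("greedy LD pruning keeps the lower-p variant of a correlated pair", {
  m <- quant_meta()
  cand <- association_table(
    rsid = c("rsA", "rsB"), effect_allele = c("C", "A"),
    other_allele = c("A", "G"), eaf = c(0.3, 0.4),
    beta = c(0.1, 0.1), se = c(0.01, 0.01),
    pvalue = c(1e-10, 1e-9), meta = m)
  ld <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2), c("rsA", "rsB"))
  sel <- select_instruments(cand, selection_criteria(), ld)
  expect_equal(sel$assocs$rsid, "rsA")
  expect_match(sel$selection_log$reason[sel$selection_log$rsid == "rsB"],
               "LD r2")
  # row order of the candidates does not change the result
  sel2 <- select_instruments(cand[2:1, ], selection_criteria(), ld)
  expect_equal(sel2$assocs$rsid, "rsA")
})

test_that("selection handles edge cases", {
  m <- quant_meta()
  empty <- association_table(character(0), character(0), character(0),
                             numeric(0), numeric(0), numeric(0),
                             numeric(0), m)
  sel <- select_instruments(empty, selection_criteria(),
                            ld_matrix(diag(1), "rs1"))
  expect_equal(nrow(sel$assocs), 0)
  expect_equal(nrow(sel$selection_log), 0)

  weak <- association_table("rs1", "C", "A", 0.005, 0.1, 0.01, 1e-10, m)
  sel <- select_instruments(weak, selection_criteria(),
                            ld_matrix(diag(1), "rs1"))
  expect_equal(sel$selection_log$reason, "MAF <= threshold")

  # candidate missing from the LD matrix is a configuration error
  ok <- association_table("rs9", "C", "A", 0.3, 0.1, 0.01, 1e-10, m)
  expect_error(select_instruments(ok, selection_criteria(),
                                  ld_matrix(diag(1), "rs1")),
               "rs9")
})

test_that("harmonization matches outcome orientation to the exposure allele", {
  m <- quant_meta("IL-6"); mo <- quant_meta("Y")
  e <- association_table("rs1", "C", "A", 0.38, 0.17, 0.012, 1e-20, m)

  same <- association_table("rs1", "C", "A", 0.38, -0.05, 0.01, 0.01, mo)
  h <- harmonize_pair(e, same)
  expect_equal(h$orientation_action, "none")
  expect_equal(h$outcome_beta, -0.05)

  swapped <- association_table("rs1", "A", "C", 0.62, 0.05, 0.01, 0.01, mo)
  h <- harmonize_pair(e, swapped)
  expect_equal(h$orientation_action, "allele_swap")
  expect_equal(h$outcome_beta, -0.05)
  expect_equal(h$outcome_eaf, 0.38)

  flipped <- association_table("rs1", "G", "T", 0.38, -0.05, 0.01, 0.01, mo)
  h <- harmonize_pair(e, flipped)
  expect_equal(h$orientation_action, "strand_flip")
  expect_equal(h$outcome_beta, -0.05)

  both <- association_table("rs1", "T", "G", 0.62, 0.05, 0.01, 0.01, mo)
  h <- harmonize_pair(e, both)
  expect_equal(h$orientation_action, "strand_flip_and_swap")
  expect_equal(h$outcome_beta, -0.05)

  other <- association_table("rs1", "C", "G", 0.38, 0.05, 0.01, 0.01, mo)
  expect_error(harmonize_pair(e, other), "incompatible")
  e2 <- association_table("rs2", "C", "A", 0.38, 0.17, 0.012, 1e-20, m)
  expect_error(harmonize_pair(e2, same), "rsid mismatch")
})

test_that("palindromic pairs follow the configured policy", {
  m <- quant_meta("IL-6"); mo <- quant_meta("Y")
  e <- association_table("rs1", "A", "T", 0.20, 0.17, 0.012, 1e-20, m)
  o_same <- association_table("rs1", "A", "T", 0.21, 0.05, 0.01, 0.01, mo)
  o_flip <- association_table("rs1", "A", "T", 0.80, 0.05, 0.01, 0.01, mo)
  expect_error(harmonize_pair(e, o_same), "ambiguous")
  h <- harmonize_pair(e, o_same, palindromic_policy = "infer_by_eaf")
  expect_equal(h$outcome_beta, 0.05)
  h <- harmonize_pair(e, o_flip, palindromic_policy = "infer_by_eaf")
  expect_equal(h$outcome_beta, -0.05)
  expect_equal(h$outcome_eaf, 0.20)
  # both frequencies near 0.5: orientation is refused
  e50 <- association_table("rs1", "A", "T", 0.47, 0.17, 0.012, 1e-20, m)
  o50 <- association_table("rs1", "A", "T", 0.55, 0.05, 0.01, 0.01, mo)
  expect_error(harmonize_pair(e50, o50, palindromic_policy = "infer_by_eaf"),
               "0.5")
})

test_that("alignment to the exposure-increasing allele is idempotent and
           preserves the Wald ratio", {
  p <- make_pair(-0.17, 0.012, 0.05, 0.01, effect_allele = "A",
                 other_allele = "C", exposure_eaf = 0.62,
                 outcome_eaf = 0.62)
  a <- align_to_increasing(p)
  expect_equal(a$exposure_beta, 0.17)
  expect_equal(a$outcome_beta, -0.05)
  expect_equal(a$effect_allele, "C")
  expect_equal(a$exposure_eaf, 0.38)
  expect_equal(align_to_increasing(a), a)     # idempotent
  expect_equal(a$outcome_beta / a$exposure_beta,
               p$outcome_beta / p$exposure_beta)
  up <- make_pair(0.17, 0.012, 0.05, 0.01)
  expect_equal(align_to_increasing(up), up)   # already aligned: unchanged
})

test_that("LD matrices read from wide and long TSVs agree", {
  long <- read_ld(targetmr_example("ld_synthetic.tsv"))
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- long$r2
  write.table(data.frame(rsid = rownames(m), m, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- read_ld(f)
  expect_equal(wide$r2[long$rsids, long$rsids], long$r2)
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.4, 1), 2), c("a", "b")),
               "symmetric")
  expect_error(ld_matrix(matrix(c(1, 1.2, 1.2, 1), 2), c("a", "b")),
               "\\[0, 1\\]")
})
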