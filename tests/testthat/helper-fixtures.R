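# Shared fixture builders. All data are constructed in code; the printed
# association tables also ship as TSVs under inst/extdata for I/O tests.

# A harmonized exposure-outcome pair assembled directly (bypassing
# harmonize_pair) for estimator unit tests.
make_pair <- function(exposure_beta, exposure_se, outcome_beta, outcome_se,
                      rsid = "rs1", effect_allele = "C", other_allele = "A",
                      exposure_eaf = 0.38, outcome_eaf = 0.38,
                      outcome_type = "binary",
                      exposure = "X", outcome = "Y") {
  data.frame(
    rsid = rsid, effect_allele = effect_allele, other_allele = other_allele,
    exposure_beta = exposure_beta, exposure_se = exposure_se,
    exposure_eaf = exposure_eaf, outcome_beta = outcome_beta,
    outcome_se = outcome_se, outcome_eaf = outcome_eaf,
    palindromic = is_palindromic(effect_allele, other_allele),
    orientation_action = "none", exposure = exposure, outcome = outcome,
    outcome_type = outcome_type, stringsAsFactors = FALSE
  )
}

# CHD pairs built from the published tables (IL-6 exposure over the two
# instruments) via the package's own harmonization path.
chd_pairs <- function() {
  align_to_increasing(harmonize(il6_associations(),
                                outcome_associations("CHD")))
}

quant_meta <- function(trait = "X", n = 10000) {
  study_meta("test", trait, "quantitative", n = n)
}

# Random single-variant association rows for property loops.
random_assoc <- function(n, trait = "X", trait_type = "quantitative") {
  alleles <- list(c("C", "A"), c("A", "G"), c("T", "C"), c("G", "T"))
  pick <- sample(length(alleles), n, replace = TRUE)
  meta <- if (trait_type == "binary")
    study_meta("test", trait, "binary", n_cases = 500, n_controls = 500)
  else quant_meta(trait)
  association_table(
    rsid = paste0("rs", seq_len(n)),
    effect_allele = vapply(alleles[pick], `[`, "", 1),
    other_allele = vapply(alleles[pick], `[`, "", 2),
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.2),
    se = runif(n, 0.005, 0.05),
    pvalue = runif(n, 1e-12, 1),
    meta = meta
  )
}

table1_variants <- function() {
  data.frame(rsid = c("rs2228145", "rs12048091"),
             eaf = c(0.38, 0.82), beta = c(0.17, 0.09),
             stringsAsFactors = FALSE)
}
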