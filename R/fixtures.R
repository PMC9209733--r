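#' Published IL-6 instrument associations
#'
#' The two cis instruments in the IL-6R region used to proxy IL-6R
#' blockade, with their published associations with circulating IL-6
#' level (standardized; ~30,000 Europeans), aligned to the
#' IL-6-increasing allele: rs2228145 (C/A, EAF 0.38, beta 0.17, SE 0.012)
#' and rs12048091 (A/G, EAF 0.82, beta 0.09, SE 0.016).
#'
#' @return Association data frame with two rows.
#' @export
il6_associations <- function() {
  meta <- study_meta("IL-6 GWAS", "IL-6", "quantitative", n = 30000)
  association_table(
    rsid = c("rs2228145", "rs12048091"),
    effect_allele = c("C", "A"), other_allele = c("A", "G"),
    eaf = c(0.38, 0.82), beta = c(0.17, 0.09), se = c(0.012, 0.016),
    pvalue = c(3.34e-45, 3.95e-8), meta = meta
  )
}

#' Published outcome associations for the IL-6 instruments
#'
#' Per-variant associations of rs2228145 and rs12048091 with the two
#' downstream biomarkers (CRP and fibrinogen, standardized, UK Biobank
#' n = 361,194) and the two positive-control diseases (rheumatoid
#' arthritis and coronary heart disease, log-odds scale), aligned to the
#' IL-6-increasing allele. Case/control counts for the disease GWASs are
#' not published and are `NA`.
#'
#' @param trait One of `"CRP"`, `"fibrinogen"`, `"RA"`, `"CHD"`.
#' @return Association data frame with two rows.
#' @export
outcome_associations <- function(trait = c("CRP", "fibrinogen", "RA",
                                           "CHD")) {
  trait <- match.arg(trait)
  meta <- switch(trait,
    CRP = study_meta("UK Biobank", "CRP", "quantitative", n = 361194),
    fibrinogen = study_meta("UK Biobank", "fibrinogen", "quantitative",
                            n = 361194),
    RA = study_meta("RA GWAS", "RA", "binary"),
    CHD = study_meta("CHD GWAS", "CHD", "binary")
  )
  vals <- switch(trait,
    CRP = list(beta = c(-0.09, -0.06), se = c(0.002, 0.003),
               p = c(1e-200, 4.36e-65)),
    fibrinogen = list(beta = c(-0.01, -0.01), se = c(0.003, 0.004),
                      p = c(0.001, 0.013)),
    RA = list(beta = c(-0.07, -0.09), se = c(0.015, 0.021),
              p = c(4.5e-6, 1.3e-5)),
    CHD = list(beta = c(-0.05, 0.02), se = c(0.010, 0.013),
               p = c(1.86e-7, 0.243))
  )
  association_table(
    rsid = c("rs2228145", "rs12048091"),
    effect_allele = c("C", "A"), other_allele = c("A", "G"),
    eaf = c(0.38, 0.82), beta = vals$beta, se = vals$se, pvalue = vals$p,
    meta = meta
  )
}

#' Published per-cohort NAFLD odds ratios
#'
#' The per-cohort MR results for NAFLD as published (odds ratio with 95%
#' CI per SD of IL-6), for the single-instrument (rs2228145) analysis:
#' non-FinnGen 1.99 (1.27, 3.13) from 1,483 cases / 17,781 controls and
#' FinnGen 1.51 (0.84, 2.72) from 894 cases / 217,898 controls. Use
#' [reconstruct_estimate()] rows (see [nafld_cohort_estimates()]) to pool
#' them.
#'
#' @return Data frame with columns `cohort`, `n_snps`, `or`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_controls`.
#' @export
nafld_cohort_or <- function() {
  data.frame(
    cohort = c("non-FinnGen", "FinnGen"),
    n_snps = c(1L, 1L),
    or = c(1.99, 1.51), ci_low = c(1.27, 0.84), ci_high = c(3.13, 2.72),
    n_cases = c(1483, 894), n_controls = c(17781, 217898),
    stringsAsFactors = FALSE
  )
}

#' Reconstructed per-cohort NAFLD estimates on the log-odds scale
#'
#' Inverts the published odds ratios and confidence intervals of
#' [nafld_cohort_or()] into log-odds estimates with normal-approximation
#' SEs, ready for [pool_fixed()] / [pool_estimates()].
#'
#' @return Data frame with one estimate row per cohort.
#' @export
nafld_cohort_estimates <- function() {
  tab <- nafld_cohort_or()
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    reconstruct_estimate(tab$or[i], tab$ci_low[i], tab$ci_high[i],
                         exposure = "IL-6", outcome = "NAFLD",
                         method = paste0("wald_ratio[", tab$cohort[i], "]"),
                         n_snps = tab$n_snps[i])
  }))
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or a vector of file names).
#' @export
targetmr_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "targetmr")))
  path <- system.file("extdata", file, package = "targetmr")
  if (!nzchar(path)) stop("no example file '", file, "'")
  path
}
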