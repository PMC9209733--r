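# Assemble the standard estimate row: normal CI, two-sided normal p, and
# odds-scale fields when the outcome is binary.
.mr_estimate <- function(method, beta, se, ci_level, n_snps,
                         exposure, outcome, binary) {
  stopifnot(se > 0, ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
    odds_ratio = if (binary) exp(beta) else NA_real_,
    or_ci_low = if (binary) exp(ci_low) else NA_real_,
    or_ci_high = if (binary) exp(ci_high) else NA_real_,
    n_snps = n_snps, exposure = exposure, outcome = outcome,
    stringsAsFactors = FALSE
  )
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The single-instrument causal effect is the ratio of the outcome
#' association to the exposure association, `outcome_beta /
#' exposure_beta`, in outcome units per SD of exposure (log-odds per SD
#' for binary outcomes). Its standard error is, by the delta method,
#' either first order (`outcome_se / |exposure_beta|`, ignoring exposure
#' uncertainty) or second order (adding the exposure-side term
#' `outcome_beta^2 * exposure_se^2 / exposure_beta^4` under the square
#' root). Confidence bounds use the normal approximation; the p-value is
#' two-sided normal. Odds-scale fields are populated when the outcome is
#' binary.
#'
#' @param pair One-row harmonized pair (see [harmonize_pair()]).
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @param ci_level Confidence level (default 0.95).
#' @return One-row data frame with `method`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `n_snps`, `exposure`, `outcome`.
#' @examples
#' pair <- data.frame(rsid = "rs2228145", effect_allele = "C",
#'   other_allele = "A", exposure_beta = 0.17, exposure_se = 0.012,
#'   exposure_eaf = 0.38, outcome_beta = -0.05, outcome_se = 0.010,
#'   outcome_eaf = NA, palindromic = FALSE, orientation_action = "none",
#'   exposure = "IL-6", outcome = "CHD", outcome_type = "binary")
#' wald_ratio(pair)  # OR about 0.75
#' @export
wald_ratio <- function(pair, se_method = c("first_order", "second_order"),
                       ci_level = 0.95) {
  se_method <- match.arg(se_method)
  p <- as.list(pair[1, ])
  if (p$exposure_beta == 0)
    stop("Wald ratio undefined: exposure beta is zero for ", p$rsid)
  beta <- p$outcome_beta / p$exposure_beta
  se <- if (se_method == "first_order") {
    p$outcome_se / abs(p$exposure_beta)
  } else {
    sqrt(p$outcome_se^2 / p$exposure_beta^2 +
           p$outcome_beta^2 * p$exposure_se^2 / p$exposure_beta^4)
  }
  .mr_estimate("wald_ratio", beta, se, ci_level, 1L,
               p$exposure, p$outcome, identical(p$outcome_type, "binary"))
}

#' Inverse-variance-weighted causal estimate from multiple instruments
#'
#' Pools the per-variant Wald ratios with precision weights derived from
#' the first-order SEs: weight `w_j = exposure_beta_j^2 / outcome_se_j^2`,
#' pooled beta `sum(w * ratio) / sum(w)`, SE `1 / sqrt(sum(w))`
#' (fixed-effect, no multiplicative residual-error scaling). Instruments
#' are treated as uncorrelated. With a single pair the result equals
#' [wald_ratio()] with first-order SE.
#'
#' @param pairs Harmonized pairs, one row per instrument.
#' @param ci_level Confidence level (default 0.95).
#' @return One-row data frame as in [wald_ratio()], with `method = "ivw"`
#'   and `n_snps` the number of instruments.
#' @export
ivw <- function(pairs, ci_level = 0.95) {
  if (nrow(pairs) == 0) stop("ivw requires at least one instrument")
  if (any(pairs$exposure_beta == 0))
    stop("Wald ratio undefined: exposure beta is zero for ",
         paste(pairs$rsid[pairs$exposure_beta == 0], collapse = ", "))
  ratio <- pairs$outcome_beta / pairs$exposure_beta
  w <- pairs$exposure_beta^2 / pairs$outcome_se^2
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  binary <- all(pairs$outcome_type == "binary")
  if (length(unique(pairs$outcome_type)) > 1)
    stop("instruments mix binary and quantitative outcomes")
  .mr_estimate("ivw", beta, se, ci_level, nrow(pairs),
               pairs$exposure[1], pairs$outcome[1], binary)
}

#' Instrument-strength F statistic
#'
#' In the single-variant summary-data setting the F statistic equals the
#' squared association z-score, `(beta / se)^2`. Values above 10 are the
#' conventional threshold for adequate instrument strength.
#'
#' @param assocs Association table (exposure side); vectorized over rows.
#' @return Numeric vector of F statistics, named by rsID.
#' @examples
#' m <- study_meta("IL-6 GWAS", "IL-6", "quantitative", n = 30000)
#' a <- association_table("rs2228145", "C", "A", 0.38, 0.17, 0.012,
#'                        3.34e-45, m)
#' f_statistic(a)  # about 200.7
#' @export
f_statistic <- function(assocs) {
  stats::setNames((assocs$beta / assocs$se)^2, assocs$rsid)
}

#' Effect of the exposure on a downstream biomarker, per SD of exposure
#'
#' Scales a quantitative biomarker association by the exposure association
#' for the same variant: the Wald ratio on the SD scale, i.e. the
#' biomarker change in SD per SD increase in the exposure, with
#' first-order SE and normal CI. No odds-scale fields are produced.
#'
#' @param exposure_rec,biomarker_rec One-row association tables sharing an
#'   rsID; both traits must be quantitative.
#' @param ci_level Confidence level (default 0.95).
#' @return One-row estimate data frame as in [wald_ratio()].
#' @export
scaled_biomarker_effect <- function(exposure_rec, biomarker_rec,
                                    ci_level = 0.95) {
  if (!identical(exposure_rec$trait_type[1], "quantitative") ||
      !identical(biomarker_rec$trait_type[1], "quantitative"))
    stop("scaled_biomarker_effect requires two quantitative traits")
  pair <- harmonize_pair(exposure_rec, biomarker_rec)
  wald_ratio(pair, se_method = "first_order", ci_level = ci_level)
}
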