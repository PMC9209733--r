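#' Variance of a standardized exposure explained by instruments
#'
#' For a biallelic variant with effect-allele frequency `p` and per-allele
#' effect `beta` on an exposure standardized to unit variance, the
#' explained variance is `2 p (1 - p) beta^2`. Multiple variants are
#' summed under the independence assumption.
#'
#' @param eaf Effect-allele frequencies in (0,1); vectorized.
#' @param beta Per-allele effects in SD units; vectorized.
#' @return Total explained variance (a fraction).
#' @examples
#' instrument_r2(0.38, 0.17)               # rs2228145-like, about 0.0136
#' instrument_r2(c(0.38, 0.82), c(0.17, 0.09))  # two-instrument total
#' @export
instrument_r2 <- function(eaf, beta) {
  stopifnot(length(eaf) == length(beta), all(eaf > 0), all(eaf < 1))
  r2 <- sum(2 * eaf * (1 - eaf) * beta^2)
  if (r2 >= 1)
    stop("explained variance >= 1; exposure effects are not on a ",
         "standardized (unit-variance) scale")
  r2
}

#' Define a power-calculation scenario for a binary outcome
#'
#' @param n Outcome-study sample size (cases + controls), persons.
#' @param case_fraction Proportion of cases K in (0,1).
#' @param or_per_sd Hypothesized causal odds ratio per SD of exposure.
#' @param r2 Variance of the exposure explained by the instrument(s); see
#'   [instrument_r2()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param label Optional scenario label.
#' @return One-row data frame of class `power_scenario`.
#' @export
power_scenario <- function(n, case_fraction, or_per_sd, r2, alpha = 0.05,
                           label = NA_character_) {
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1, or_per_sd > 0,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  structure(data.frame(label = label, n = n, case_fraction = case_fraction,
                       or_per_sd = or_per_sd, r2 = r2, alpha = alpha,
                       stringsAsFactors = FALSE),
            class = c("power_scenario", "data.frame"))
}

#' Analytic power for MR with a binary outcome
#'
#' Non-centrality-parameter calculation for a two-sample MR test of a
#' causal odds ratio per SD of exposure. With case fraction `K`, odds
#' ratio `OR`, outcome sample size `n` and instrument `r2`, the attenuated
#' risk-difference scale effect is `b = K (OR / (1 + K (OR - 1)) - 1)`,
#' its variance `v = (K (1 - K) - b^2) / (n r2)`, and the test statistic
#' is non-central chi-square(1) with `NCP = b^2 / v`; power is the
#' probability of exceeding the central chi-square critical value at
#' `alpha`. At `OR = 1` the power equals `alpha`.
#'
#' @param scenario A [power_scenario()] (or a data frame with its
#'   columns; vectorized over rows).
#' @return Numeric vector of power values in (0, 1).
#' @examples
#' s <- power_scenario(n = 19264, case_fraction = 1483 / 19264,
#'                     or_per_sd = 1.99, r2 = instrument_r2(0.38, 0.17))
#' binary_mr_power(s)  # about 0.98
#' @export
binary_mr_power <- function(scenario) {
  stopifnot(all(c("n", "case_fraction", "or_per_sd", "r2", "alpha") %in%
                  names(scenario)))
  K <- scenario$case_fraction
  OR <- scenario$or_per_sd
  b <- K * (OR / (1 + K * (OR - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (scenario$n * scenario$r2)
  ncp <- b^2 / v
  if (any(!is.finite(ncp))) stop("non-finite non-centrality parameter")
  crit <- stats::qchisq(1 - scenario$alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Tabulate power across scenarios
#'
#' @param scenarios Data frame of scenarios (rows as in
#'   [power_scenario()]).
#' @return The scenarios with a `power` column appended.
#' @export
power_table <- function(scenarios) {
  scenarios$power <- binary_mr_power(scenarios)
  scenarios
}
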