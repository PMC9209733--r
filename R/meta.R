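# Shared skeleton of a meta-analysis result row.
.meta_result <- function(model, beta, se, ci_level, q, df, tau2, k,
                         exposure, outcome, binary) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  i2 <- if (q > 0 && k > 1) max(0, (q - df) / q) * 100 else 0
  q_pvalue <- if (k > 1) stats::pchisq(q, df, lower.tail = FALSE) else 1
  data.frame(
    model = model, k = k, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    odds_ratio = if (binary) exp(beta) else NA_real_,
    or_ci_low = if (binary) exp(ci_low) else NA_real_,
    or_ci_high = if (binary) exp(ci_high) else NA_real_,
    q = q, df = df, q_pvalue = q_pvalue, i2 = i2, tau2 = tau2,
    exposure = exposure, outcome = outcome,
    stringsAsFactors = FALSE
  )
}

.check_meta_input <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("beta", "se") %in% names(estimates)))
  if (nrow(estimates) == 0) stop("no estimates to pool")
  if (any(estimates$se <= 0)) stop("all standard errors must be positive")
  if ("odds_ratio" %in% names(estimates)) {
    binary <- !is.na(estimates$odds_ratio)
    if (length(unique(binary)) > 1)
      stop("cannot pool estimates on mixed outcome scales")
  }
  invisible(estimates)
}

.meta_labels <- function(estimates) {
  lab <- function(col) {
    if (col %in% names(estimates)) {
      u <- unique(estimates[[col]])
      if (length(u) == 1) u else paste(u, collapse = "+")
    } else NA_character_
  }
  list(exposure = lab("exposure"), outcome = lab("outcome"),
       binary = "odds_ratio" %in% names(estimates) &&
         all(!is.na(estimates$odds_ratio)))
}

#' Fixed-effects meta-analysis of MR estimates
#'
#' Inverse-variance fixed-effects pooling on the log/linear scale:
#' weights `w_i = 1/se_i^2`, pooled beta the weighted mean, pooled SE
#' `1/sqrt(sum(w))`. Heterogeneity is quantified by Cochran's
#' `Q = sum(w_i * (beta_i - beta)^2)` on `k - 1` degrees of freedom and
#' `I^2 = max(0, (Q - df)/Q) * 100`. A single estimate passes through with
#' `Q = 0`, `I^2 = 0`, `q_pvalue = 1`.
#'
#' @param estimates Data frame of estimates to pool (rows from
#'   [wald_ratio()], [ivw()], or [reconstruct_estimate()]); must share one
#'   outcome scale.
#' @param ci_level Confidence level (default 0.95).
#' @return One-row data frame with `model`, `k`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, odds-scale fields when binary, `q`, `df`,
#'   `q_pvalue`, `i2`, `tau2` (0 under the fixed model), `exposure`,
#'   `outcome`.
#' @export
pool_fixed <- function(estimates, ci_level = 0.95) {
  .check_meta_input(estimates)
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates$beta - beta)^2)
  k <- nrow(estimates)
  lab <- .meta_labels(estimates)
  .meta_result("fixed", beta, se, ci_level, q, k - 1L, 0, k,
               lab$exposure, lab$outcome, lab$binary)
}

#' Random-effects (DerSimonian-Laird) meta-analysis of MR estimates
#'
#' Estimates the between-study variance by the method of moments:
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/se_i^2`, then pools with the re-weighted
#' `w*_i = 1/(se_i^2 + tau2)`. Q, df, I^2 are reported from the
#' fixed-effect weights as usual. When the estimates are homogeneous
#' (`Q <= df`) tau2 truncates to 0 and the result coincides with
#' [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return One-row data frame as in [pool_fixed()] with `model =
#'   "random"` and the estimated `tau2`.
#' @export
pool_random <- function(estimates, ci_level = 0.95) {
  .check_meta_input(estimates)
  k <- nrow(estimates)
  if (k < 2) stop("random-effects pooling requires at least 2 estimates")
  w <- 1 / estimates$se^2
  beta_fe <- sum(w * estimates$beta) / sum(w)
  q <- sum(w * (estimates$beta - beta_fe)^2)
  df <- k - 1L
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (estimates$se^2 + tau2)
  beta <- sum(w_star * estimates$beta) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  lab <- .meta_labels(estimates)
  .meta_result("random", beta, se, ci_level, q, df, tau2, k,
               lab$exposure, lab$outcome, lab$binary)
}

#' Choose fixed or random effects from the heterogeneity test
#'
#' Implements the conventional rule: pool with fixed effects unless
#' Cochran's Q is significant at `q_alpha` (a single estimate is always
#' "fixed").
#'
#' @inheritParams pool_fixed
#' @param q_alpha Significance level for the Q test (default 0.05).
#' @return `"fixed"` or `"random"`.
#' @export
decide_model <- function(estimates, q_alpha = 0.05) {
  .check_meta_input(estimates)
  if (nrow(estimates) == 1) return("fixed")
  fe <- pool_fixed(estimates)
  if (fe$q_pvalue > q_alpha) "fixed" else "random"
}

#' Pool estimates under a model policy
#'
#' Convenience wrapper: `"auto"` applies [decide_model()], otherwise the
#' stated model is used.
#'
#' @inheritParams pool_fixed
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param q_alpha Passed to [decide_model()] under `"auto"`.
#' @return One-row meta-analysis result.
#' @export
pool_estimates <- function(estimates, model = c("auto", "fixed", "random"),
                           ci_level = 0.95, q_alpha = 0.05) {
  model <- match.arg(model)
  if (model == "auto") model <- decide_model(estimates, q_alpha)
  if (model == "fixed") pool_fixed(estimates, ci_level)
  else pool_random(estimates, ci_level)
}

#' Reconstruct a log-scale estimate from a published OR and CI
#'
#' Publications usually report an odds ratio with a 95% confidence
#' interval rather than the underlying log-odds and SE. This inverts the
#' normal-approximation CI: `beta = log(or)` and `se = log(ci_high /
#' ci_low) / (2 z)`.
#'
#' @param or Odds ratio.
#' @param ci_low,ci_high Confidence bounds on the odds-ratio scale.
#' @param ci_level Level of the published interval (default 0.95).
#' @param exposure,outcome,method Labels carried into the estimate row.
#' @param n_snps Number of instruments behind the published estimate.
#' @return One-row estimate data frame compatible with [pool_fixed()].
#' @examples
#' reconstruct_estimate(1.99, 1.27, 3.13, outcome = "NAFLD")
#' @export
reconstruct_estimate <- function(or, ci_low, ci_high, ci_level = 0.95,
                                 exposure = NA_character_,
                                 outcome = NA_character_,
                                 method = "reconstructed",
                                 n_snps = NA_integer_) {
  stopifnot(or > 0, ci_low > 0, ci_high > ci_low)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  beta <- log(or)
  se <- log(ci_high / ci_low) / (2 * z)
  .mr_estimate(method, beta, se, ci_level, n_snps, exposure, outcome,
               binary = TRUE)
}
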