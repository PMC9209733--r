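#' Configure a two-sample synthetic GWAS study
#'
#' Describes the generative model for a pair of non-overlapping cohorts:
#' an exposure cohort in which a standardized quantitative exposure is
#' scanned, and an outcome cohort in which a binary outcome generated from
#' a logistic model is scanned. Genotypes are Hardy-Weinberg biallelic
#' dosages with configurable effect-allele frequencies and pairwise
#' dosage correlations (via a calibrated Gaussian copula). The exposure is
#' an additive genetic score plus Gaussian noise scaled so its total
#' variance is 1; the outcome is Bernoulli with log-odds `intercept +
#' gamma * exposure + direct_effects . dosage`.
#'
#' @param n_exposure,n_outcome Cohort sizes, persons.
#' @param variants Data frame with columns `rsid`, `eaf`, `beta`
#'   (per-allele effect on the exposure, SD units) and optionally
#'   `effect_allele`, `other_allele` (defaults C/A... sequential
#'   non-palindromic pairs).
#' @param pairwise_r Target correlation between variant dosages: a scalar
#'   applied to every pair, or a full symmetric matrix. Default 0
#'   (independent variants).
#' @param gamma Causal log-odds of the outcome per SD of exposure.
#' @param intercept Baseline log-odds of the outcome (sets prevalence).
#' @param direct_effects Per-variant pleiotropic log-odds per allele
#'   (scalar or vector; default 0, satisfying the exclusion restriction).
#' @param seed Integer seed; all randomness in [generate_study()] flows
#'   from it.
#' @return A list of class `simulation_config`.
#' @examples
#' simulation_config(1000, 1000,
#'   variants = data.frame(rsid = c("v1", "v2"), eaf = c(0.38, 0.82),
#'                         beta = c(0.17, 0.09)),
#'   gamma = 0.6, intercept = -2.5, seed = 1)
#' @export
simulation_config <- function(n_exposure, n_outcome, variants,
                              pairwise_r = 0, gamma = 0, intercept = -2.5,
                              direct_effects = 0, seed = 1) {
  stopifnot(is.data.frame(variants),
            all(c("rsid", "eaf", "beta") %in% names(variants)),
            n_exposure >= 10, n_outcome >= 10)
  m <- nrow(variants)
  if (any(variants$eaf <= 0 | variants$eaf >= 1))
    stop("variant eafs must lie strictly in (0, 1)")
  if (!"effect_allele" %in% names(variants)) {
    pool <- list(c("C", "A"), c("A", "G"), c("T", "C"), c("G", "A"))
    pick <- pool[((seq_len(m) - 1) %% length(pool)) + 1]
    variants$effect_allele <- vapply(pick, `[`, "", 1)
    variants$other_allele <- vapply(pick, `[`, "", 2)
  }
  if (is.matrix(pairwise_r)) {
    R <- pairwise_r
    stopifnot(nrow(R) == m, ncol(R) == m)
  } else {
    R <- matrix(pairwise_r, m, m)
  }
  diag(R) <- 1
  if (any(abs(R - t(R)) > 1e-8)) stop("pairwise_r must be symmetric")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("pairwise_r is not positive semi-definite")
  direct_effects <- rep_len(direct_effects, m)
  structure(list(n_exposure = n_exposure, n_outcome = n_outcome,
                 variants = variants, pairwise_r = R, gamma = gamma,
                 intercept = intercept, direct_effects = direct_effects,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Phi (Pearson) correlation between two allele indicators dichotomized at
# qnorm(p1), qnorm(p2) from a bivariate normal with latent correlation rho.
.phi_from_latent <- function(rho, p1, p2) {
  t1 <- stats::qnorm(p1)
  t2 <- stats::qnorm(p2)
  p11 <- stats::integrate(function(z) {
    stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  }, -Inf, t1, rel.tol = 1e-10)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent Gaussian correlation that yields a target dosage correlation after
# dichotomization at the allele frequencies (copula calibration).
.latent_rho <- function(target, p1, p2) {
  if (abs(target) < 1e-12) return(0)
  f <- function(rho) .phi_from_latent(rho, p1, p2) - target
  lo <- max(-0.9999, -1 + 1e-4)
  hi <- 0.9999
  if (f(hi) < 0 || f(lo) > 0)
    stop("target dosage correlation ", target,
         " is unattainable at allele frequencies ", p1, ", ", p2)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# Latent correlation matrix matching the configured dosage correlations.
.latent_matrix <- function(config) {
  R <- config$pairwise_r
  p <- config$variants$eaf
  m <- nrow(R)
  L <- diag(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j > i)
      L[i, j] <- L[j, i] <- .latent_rho(R[i, j], p[i], p[j])
  }
  L
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws 0/1/2 dosages for `n` persons at the configured variants. Each
#' person receives two independent haplotypes; each haplotype is a
#' thresholded multivariate Gaussian whose latent correlation is
#' calibrated so the realized dosage correlations match
#' `config$pairwise_r` in expectation, while marginal allele frequencies
#' match `config$variants$eaf`.
#'
#' @param config A [simulation_config()].
#' @param n Number of persons (defaults to the exposure cohort size).
#' @return Integer matrix, persons by variants, with rsIDs as column
#'   names. Uses the current RNG state; [generate_study()] seeds it.
#' @export
simulate_genotypes <- function(config, n = config$n_exposure) {
  stopifnot(inherits(config, "simulation_config"))
  m <- nrow(config$variants)
  L <- .latent_matrix(config)
  ch <- tryCatch(chol(L), error = function(e)
    stop("latent correlation matrix is not positive definite"))
  thresholds <- stats::qnorm(config$variants$eaf)
  haplo <- function() {
    z <- matrix(stats::rnorm(n * m), n, m) %*% ch
    sweep(z, 2, thresholds, "<") * 1L
  }
  g <- haplo() + haplo()
  colnames(g) <- config$variants$rsid
  g
}

#' Simulate exposure and outcome from genotype dosages
#'
#' The exposure is the centered additive genetic score plus Gaussian noise
#' with variance `1 - var_genetic`, so the exposure has unit variance in
#' expectation (an error is raised if the genetic variance implied by the
#' configuration reaches 1). The outcome is Bernoulli with log-odds
#' `intercept + gamma * exposure + direct_effects . dosage`.
#'
#' @param dosages Matrix from [simulate_genotypes()].
#' @param config A [simulation_config()].
#' @return List with numeric `exposure` and integer `outcome` vectors.
#' @export
simulate_traits <- function(dosages, config) {
  stopifnot(inherits(config, "simulation_config"))
  v <- config$variants
  p <- v$eaf
  sd_g <- sqrt(2 * p * (1 - p))
  Sigma <- config$pairwise_r * tcrossprod(sd_g)
  var_g <- as.numeric(t(v$beta) %*% Sigma %*% v$beta)
  if (var_g >= 1)
    stop("genetic variance of the exposure (", round(var_g, 4),
         ") must be below 1 for a standardized exposure")
  n <- nrow(dosages)
  score <- as.vector(sweep(dosages, 2, 2 * p, "-") %*% v$beta)
  exposure <- score + stats::rnorm(n, sd = sqrt(1 - var_g))
  eta <- config$intercept + config$gamma * exposure +
    as.vector(dosages %*% config$direct_effects)
  outcome <- stats::rbinom(n, 1, stats::plogis(eta))
  list(exposure = exposure, outcome = outcome)
}

# Closed-form simple linear regression of y on each dosage column.
.scan_quantitative <- function(dosages, y) {
  n <- nrow(dosages)
  gc <- sweep(dosages, 2, colMeans(dosages), "-")
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  beta <- sxy / sxx
  rss <- pmax(sum(yc^2) - beta^2 * sxx, 0)  # per-variant residual SS
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, pvalue = p)
}

# Univariate logistic regression of y on each dosage column.
.scan_binary <- function(dosages, y) {
  m <- ncol(dosages)
  beta <- se <- p <- numeric(m)
  for (j in seq_len(m)) {
    fit <- stats::glm.fit(cbind(1, dosages[, j]), y,
                          family = stats::binomial())
    cov <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(cov[2, 2])
    p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
  }
  list(beta = beta, se = se, pvalue = p)
}

#' Per-variant association scan of a simulated trait
#'
#' Runs a univariate association test per variant — simple linear
#' regression for a quantitative trait, logistic regression for a binary
#' one — and returns the results as a canonical association table with
#' empirical allele frequencies and cohort sizes. Monomorphic variants
#' cannot be tested and are skipped with a message.
#'
#' @param dosages Matrix from [simulate_genotypes()].
#' @param trait Numeric (quantitative) or 0/1 (binary) vector, one entry
#'   per row of `dosages`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param variants Data frame supplying `rsid`, `effect_allele`,
#'   `other_allele` for the columns of `dosages`.
#' @param trait_label Trait name stamped on the records.
#' @return Association data frame (see [read_associations()] for the
#'   layout).
#' @export
summary_scan <- function(dosages, trait,
                         trait_type = c("quantitative", "binary"),
                         variants, trait_label = "trait") {
  trait_type <- match.arg(trait_type)
  stopifnot(nrow(dosages) == length(trait), ncol(dosages) == nrow(variants))
  mono <- apply(dosages, 2, function(g) stats::var(g) == 0)
  if (any(mono)) {
    message("skipping monomorphic variant(s): ",
            paste(variants$rsid[mono], collapse = ", "))
    dosages <- dosages[, !mono, drop = FALSE]
    variants <- variants[!mono, , drop = FALSE]
  }
  if (ncol(dosages) == 0)
    stop("no polymorphic variants to scan")
  res <- if (trait_type == "quantitative") .scan_quantitative(dosages, trait)
         else .scan_binary(dosages, trait)
  n <- nrow(dosages)
  meta <- if (trait_type == "binary") {
    study_meta("simulated", trait_label, "binary",
               n_cases = sum(trait), n_controls = n - sum(trait))
  } else {
    study_meta("simulated", trait_label, "quantitative", n = n)
  }
  association_table(
    rsid = variants$rsid,
    effect_allele = variants$effect_allele,
    other_allele = variants$other_allele,
    eaf = colMeans(dosages) / 2,
    beta = res$beta, se = res$se, pvalue = pmax(res$pvalue, 1e-300),
    meta = meta
  )
}

#' Generate a complete two-sample synthetic study
#'
#' Seeds the RNG from the configuration, draws the exposure cohort
#' (genotypes, exposure, exposure scan), then draws an independent outcome
#' cohort (genotypes, exposure, outcome, outcome scan) — the two cohorts
#' share no individuals, as required by two-sample MR. The sample LD
#' matrix (squared dosage correlations) is computed from the exposure
#' cohort. Identical seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `exposure.tsv`,
#'   `outcome.tsv` and `ld.tsv` are written there in the canonical
#'   dialect, directly consumable by [run_pipeline()].
#' @return A list of class `simulated_study` with `exposure_assocs`,
#'   `outcome_assocs`, `ld` (an [ld_matrix()] of sample r-squared),
#'   `truth` (the generative parameters) and `seed`.
#' @export
generate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g_exp <- simulate_genotypes(config, config$n_exposure)
  t_exp <- simulate_traits(g_exp, config)
  exposure_assocs <- summary_scan(g_exp, t_exp$exposure, "quantitative",
                                  config$variants, trait_label = "exposure")
  g_out <- simulate_genotypes(config, config$n_outcome)
  t_out <- simulate_traits(g_out, config)
  outcome_assocs <- summary_scan(g_out, t_out$outcome, "binary",
                                 config$variants, trait_label = "outcome")
  r2 <- stats::cor(g_exp)^2
  diag(r2) <- 1
  r2[r2 > 1] <- 1
  ld <- ld_matrix(r2, config$variants$rsid)
  study <- structure(
    list(exposure_assocs = exposure_assocs,
         outcome_assocs = outcome_assocs, ld = ld,
         truth = list(gamma = config$gamma, intercept = config$intercept,
                      variants = config$variants,
                      direct_effects = config$direct_effects),
         seed = config$seed),
    class = "simulated_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tsv <- function(df, file)
      utils::write.table(df, file.path(dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_tsv(exposure_assocs, "exposure.tsv")
    write_tsv(outcome_assocs, "outcome.tsv")
    ids <- config$variants$rsid
    long <- which(upper.tri(r2), arr.ind = TRUE)
    write_tsv(data.frame(rsid_a = ids[long[, 1]], rsid_b = ids[long[, 2]],
                         r2 = r2[long]), "ld.tsv")
  }
  study
}
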