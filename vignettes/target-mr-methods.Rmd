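---
title: "Target-based Mendelian randomization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-based Mendelian randomization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem targetmr addresses

Drug-target (cis) Mendelian randomization asks whether pharmacological
modulation of a protein would change disease risk, using naturally
occurring genetic variation in or near the gene encoding the target as a
proxy for the drug. The canonical application bundled with this package
is IL-6 receptor blockade: the missense variant rs2228145 in *IL6R*
increases proteolysis of the membrane-bound receptor, dampening classical
IL-6 signalling much as the monoclonal antibody tocilizumab does, while
raising the circulating IL-6 level through feedback. Treating the
genetically predicted IL-6 level as the exposure, two-sample MR combines
a variant's association with the exposure (from one GWAS) and with an
outcome (from an independent GWAS) into a causal estimate.

The package implements the full summary-statistics workflow around that
idea: instrument selection, harmonization, Wald-ratio/IVW estimation,
cross-cohort meta-analysis with heterogeneity statistics, instrument
strength and analytic power, and a seeded generator of synthetic
two-sample studies with known ground truth.

## Estimators

For a single instrument with exposure association $\hat\beta_X$ (SE
$\sigma_X$) and outcome association $\hat\beta_Y$ (SE $\sigma_Y$), the
**Wald ratio** is

$$\hat\theta = \hat\beta_Y / \hat\beta_X.$$

Its default standard error is the first-order delta approximation
$\sigma_Y / |\hat\beta_X|$, which ignores uncertainty in the exposure
association; the second-order form
$\sqrt{\sigma_Y^2/\hat\beta_X^2 + \hat\beta_Y^2\sigma_X^2/\hat\beta_X^4}$
adds the exposure term and therefore never undercuts the first-order SE.
First order is the default because it is the convention of the
summary-data MR software ecosystem and because with strong instruments
(F well above 10, as here: F ≈ 200 and ≈ 30) the second term is
negligible. Confidence intervals are normal-approximation intervals on
the log-odds (or SD) scale, exponentiated for reporting when the outcome
is binary; p-values are two-sided normal, identical to the
chi-square(1 df) tail of the squared z-score.

With $k$ instruments the **IVW** estimate is the precision-weighted mean
of the per-variant Wald ratios with first-order weights
$w_j = \hat\beta_{X_j}^2/\sigma_{Y_j}^2$, SE $1/\sqrt{\sum w_j}$. It is
a fixed-effect combination without multiplicative residual-error
scaling — with two instruments a residual scale is degenerate — and it
treats instruments as uncorrelated. The bundled IL-6 instruments have
LD $r^2 = 0.11$, which the analysis deliberately ignores, replicating
the source analysis; a correlation-aware IVW is out of scope, and the
modest positive correlation makes the reported IVW SE slightly
anti-conservative. The identity "IVW = inverse-variance fixed-effects
pooling of per-variant Wald ratios" is enforced by a cross-module test
to 1e-12.

**Instrument strength** is summarized by $F = (\hat\beta_X/\sigma_X)^2$,
the squared association z-score, the standard single-variant
summary-data form.

## Instrument selection and harmonization

Selection applies, in order: exposure significance ($p < 5\times10^{-8}$),
minor-allele frequency ($\min(p, 1-p) > 0.01$, strict inequalities
mirroring the conventional "> 0.01"), removal of palindromic (A/T, C/G)
variants, then greedy LD pruning: survivors are ranked by ascending
p-value (ties broken lexicographically by rsID, making the result
independent of input row order), the best is kept, and any later
candidate with $r^2 \ge 0.3$ against a kept variant is dropped. The
source analysis states the thresholds but not the pruning algorithm;
greedy p-ranked pruning is the standard "clumping" choice and is
deterministic. Every decision is logged per candidate.

Harmonization matches each outcome record to the exposure's allele
orientation (identity, allele swap with beta negation and frequency
complementation, strand flip, or both), then alignment re-orients every
pair to the exposure-increasing allele so that reported effects read as
"per SD increase in the exposure". Palindromic variants default to the
`drop` policy — the bundled analysis removed its palindromic candidate
outright — with `infer_by_eaf` available; frequency inference is refused
when both frequencies lie within 0.08 of 0.5, a conventional ambiguity
band. The Wald ratio is invariant under harmonization and alignment,
which the property tests check on randomized inputs.

The exposure p-value filter is applied to the reported p-value rather
than recomputed from beta/SE, keeping fidelity to source tables whose
printed p and beta/SE are rounded independently.

## Meta-analysis and heterogeneity

Per-cohort estimates for the same outcome are pooled on the log-odds
scale. Fixed effects uses weights $1/se_i^2$; heterogeneity is Cochran's
$Q$ on $k-1$ degrees of freedom and $I^2 = \max(0, (Q-df)/Q) \cdot 100$,
floored at zero per the standard definition. The random-effects model is
DerSimonian–Laird: $\tau^2 = \max(0, (Q-df)/(\sum w - \sum w^2/\sum w))$
with re-weighting $1/(se_i^2+\tau^2)$; it reduces exactly to fixed
effects when $Q \le df$. The model policy `auto` implements the
conventional rule — fixed effects unless the Q test is significant at
0.05. A single estimate yields a degenerate but well-defined result
($Q=0$, $I^2=0$, Q p-value 1) rather than an error, so the pipeline's
reporting is uniform. Back-transformation to odds ratios happens only at
reporting time. The implementation is closed-form and is cross-checked
against `metafor` in the test suite.

Published per-cohort results that exist only as "OR (95% CI)" are
re-imported by inverting the normal CI: $\beta = \log OR$,
$se = \log(CI_{high}/CI_{low})/(2z)$. For the bundled NAFLD cohorts
(1.99 [1.27, 3.13] and 1.51 [0.84, 2.72]) this reconstruction pools to
1.80 (1.26, 2.57) with $I^2 = 0$, matching the published meta-analysis
at reporting precision, which validates the reconstruction. The
published two-instrument pooled result (1.83) is not reproducible
because one cohort's two-instrument OR/CI was never printed; it is
documented here and not asserted anywhere.

## Power

Analytic power for a binary outcome follows the non-centrality-parameter
approach of the mRnd-style calculators: with case fraction $K$,
hypothesized odds ratio $OR$ per SD of exposure, outcome sample size $N$
and instrument $R^2$,

$$b = K\left(\frac{OR}{1 + K(OR-1)} - 1\right),\qquad
  v = \frac{K(1-K) - b^2}{N R^2},\qquad NCP = b^2/v,$$

and power is the mass of the noncentral chi-square(1, NCP) beyond the
central critical value at $\alpha$ (default 0.05 two-sided; at $OR = 1$
power equals $\alpha$ exactly). Instrument $R^2$ for a standardized
exposure is $2p(1-p)\beta^2$, summed over independent instruments. With
the bundled values ($N = 19{,}264$, $K = 1483/19264$, $OR = 1.99$,
$R^2 = 2\cdot0.38\cdot0.62\cdot0.17^2$) this reproduces the published
98% for the larger NAFLD cohort, which validates the formula choice (the
source names only the calculator). The published 84% for the smaller
cohort is not reproducible from any printed (N, K, OR, R²) combination
we could identify; the discrepancy is documented and no check is tied to
it. By default power uses the primary instrument's $R^2$ alone, with the
two-instrument sum available.

## The synthetic-data generator

`generate_study()` emulates the two-sample setting: two disjoint
cohorts, a standardized quantitative exposure, and a binary outcome from
a logistic model.

* **Genotypes.** Each person receives two independent haplotypes; each
  haplotype is a thresholded multivariate Gaussian. The latent
  correlation is calibrated numerically (bivariate-normal orthant
  probability inverted with `uniroot`) so the realized *dosage*
  correlations match the requested values — naive thresholding at the
  latent correlation would attenuate them. Marginal allele frequencies
  follow the configuration; Hardy–Weinberg holds per variant.
* **Exposure.** Centered additive genetic score plus Gaussian noise with
  variance $1 - \mathrm{Var}_{genetic}$, so the exposure has unit
  variance in expectation; configurations implying genetic variance ≥ 1
  are rejected.
* **Outcome.** Bernoulli with log-odds `intercept + gamma * exposure +
  direct_effects · dosage`. The logistic (not liability-probit) link
  matches odds-ratio reporting; in the small-per-allele-effect,
  low-prevalence regime used here the instrument-level outcome
  association is approximately `gamma * exposure_beta`, which is exactly
  the approximation the Wald ratio relies on. Setting `direct_effects`
  non-zero breaks the exclusion restriction on purpose.
* **Scans.** Per-variant simple linear regression (closed form) for the
  exposure cohort and univariate logistic regression for the outcome
  cohort, yielding canonical summary-statistics tables with empirical
  allele frequencies and case/control counts; monomorphic variants are
  flagged and skipped. All randomness flows from one integer seed;
  identical seeds give bit-identical output files.

What the generator does *not* emulate: population structure,
relatedness, genome-wide polygenicity, winner's curse in instrument
discovery, or assortative mating. Passing recovery tests therefore shows
the estimators are correct under the stated model, not that real-data
biases are absent.

The default parameter-recovery experiments use two instruments with the
bundled effect sizes (0.17 and 0.09 SD per allele at frequencies 0.38
and 0.82), 50,000 persons per cohort, and an outcome intercept of −2.5
(≈ 8% case fraction, matching the larger bundled outcome cohort).
Instruments are simulated uncorrelated in these experiments because the
IVW estimator under test assumes uncorrelated instruments; LD is
exercised separately by the copula-calibration tests. Replicates advance
the seed as `base + i`. Under the causal effect 0.6 the IVW 95% CI
covers the truth in well over 90 of 100 replicates; under the null the
Wald test's rejection rate sits near 0.05 (the small residual coverage
loss comes from logistic non-collapsibility, which mildly attenuates
instrument-level outcome associations at higher prevalence).

## Numerical and interface choices

* Odds ratios and CI bounds are rendered at 2 decimals in results tables
  (the field's reporting convention), with full-precision `beta`/`se`
  columns alongside; all pooling happens at full precision.
* Binary-trait case/control counts may be `NA` when a source GWAS does
  not report them (true of the bundled positive-control GWASs); the
  consistency invariant `n = n_cases + n_controls` is enforced whenever
  the counts are present.
* Strict validation is the default for bundled fixtures; `lenient` mode
  (skip-and-log) is intended for user files.
* The candidate-selection fixture includes a third, palindromic variant
  whose alleles, frequency and LD were never published; the bundled
  values for it are invented placeholders (the file is named
  `il6_candidates_synthetic.tsv` accordingly) and it is removed by the
  palindrome filter regardless.
* The pipeline is a plain function over a validated configuration list
  (optionally YAML); each stage is also an exported function, and
  composing the stages reproduces `run_pipeline()` exactly, which is
  tested. A bare `n:` key in YAML 1.1 parses as a boolean; the config
  reader restores it.

## Known limitations

Single-gene cis instruments cannot separate on-target from
linked-variant effects; the IVW here ignores the modest LD between the
two bundled instruments; power calculations assume the NCP
approximation and a correctly specified $R^2$; and reconstruction of
published estimates from rounded ORs/CIs inherits the printed rounding
(one bundled biomarker ratio, CRP for the secondary instrument, differs
from its published value by more than any rounding bound and is
documented rather than asserted).
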