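# targetmr

Target-based (cis) two-sample Mendelian randomization from GWAS summary
statistics.

## What it is for

Drug-target MR uses genetic variants in or near a gene encoding a drug
target as natural proxies for pharmacological modulation of that target.
`targetmr` implements the complete summary-statistics workflow for an
analyst running such a study:

* **Instrument selection** — genome-wide significance, minor-allele
  frequency floor, removal of palindromic (A/T, C/G) variants, greedy
  LD pruning by ascending p-value, with a per-candidate decision log.
* **Harmonization** — placing exposure and outcome associations on a
  shared effect allele (allele swaps, strand flips, EAF-based inference
  for palindromes) and aligning every pair to the exposure-increasing
  allele.
* **Causal estimation** — the Wald ratio
  `theta = beta_outcome / beta_exposure` with first- or second-order
  delta SEs, and the inverse-variance-weighted (IVW) combination of
  per-variant ratios with weights `w_j = beta_xj^2 / se_yj^2`.
* **Meta-analysis** — fixed-effects and DerSimonian–Laird
  random-effects pooling of per-cohort estimates on the log-odds scale,
  with Cochran's Q, I², and the conventional fixed-unless-heterogeneous
  model rule; published "OR (95% CI)" results can be re-imported via
  `reconstruct_estimate()`.
* **Instrument strength and power** — `F = (beta/se)^2` per variant,
  instrument `R^2 = 2p(1-p)beta^2`, and non-centrality-parameter power
  for binary outcomes.
* **Synthetic studies** — a seeded generator of two-sample cohorts
  (copula-calibrated LD, standardized exposure, logistic outcome) with
  known causal effect, used for parameter-recovery testing.
* **Pipeline** — `run_pipeline()` drives all stages from one (YAML)
  configuration and writes per-stage TSVs plus a combined results table
  and run log.

The bundled example data are the published summary associations for the
IL-6R missense variant rs2228145 and the intronic rs12048091: their
effects on circulating IL-6, on the downstream biomarkers CRP and
fibrinogen, on the positive-control diseases rheumatoid arthritis and
coronary heart disease, and per-cohort NAFLD odds ratios from two
independent case/control GWASs.

## Worked example

```r
library(targetmr)

il6 <- il6_associations()                       # exposure: IL-6 level, SD units
chd <- align_to_increasing(harmonize(il6, outcome_associations("CHD")))
wald_ratio(chd[chd$rsid == "rs2228145", ])
#>       method   beta     se odds_ratio or_ci_low or_ci_high   pvalue
#> 1 wald_ratio -0.294 0.0588      0.745     0.664      0.836 5.73e-07

pool_estimates(nafld_cohort_estimates(), "auto")
#>   model k odds_ratio or_ci_low or_ci_high     q q_pvalue i2
#> 1 fixed 2        1.8      1.26       2.57 0.534    0.465  0
```

Reading: one SD of genetically predicted IL-6 (proxied by the
IL-6-raising allele of rs2228145, so higher IL-6 here means *less* IL-6R
signalling) lowers coronary-heart-disease odds by a factor 0.75 — the
expected tocilizumab-like direction, validating the instrument. Pooling
the two NAFLD cohorts (no heterogeneity: Q p = 0.47, I² = 0, so the
auto rule picks fixed effects) gives OR 1.80 (1.26, 2.57) per SD of
IL-6: blocking IL-6R signalling is estimated to *increase* NAFLD risk.

The same analysis end to end, from files:

```r
cfg <- read_run_config(targetmr_example("paper_run.yaml"))
res <- run_pipeline(cfg, output_dir = tempfile())
res$meta
```

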