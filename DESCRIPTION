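Package: targetmr
Title: Target-Based Two-Sample Mendelian Randomization from GWAS Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target (cis) Mendelian randomization with GWAS
    summary statistics: instrument selection (significance, minor-allele
    frequency, palindrome removal, greedy LD pruning), harmonization of
    exposure and outcome associations onto a shared exposure-increasing
    effect allele, Wald-ratio and inverse-variance-weighted causal
    estimation, fixed- and random-effects (DerSimonian-Laird)
    meta-analysis with Cochran's Q and I-squared, instrument-strength F
    statistics, non-centrality-parameter power calculations for binary
    outcomes, a seeded generator of synthetic two-sample summary
    statistics with known causal effect, and a config-driven pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
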