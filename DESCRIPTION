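Package: mrpleio
Title: Two-Sample Multivariable Mendelian Randomization with Pleiotropy
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample summary-statistics Mendelian randomization
    of correlated exposures: instrument selection at genome-wide significance
    with greedy linkage-disequilibrium clumping, allele harmonization and
    orientation of GWAS summary statistics, single-SNP Wald ratios,
    univariable and multivariable inverse-variance-weighted and Egger
    regression, multivariable Cochran's Q / H-squared / I-squared
    heterogeneity, a pleiotropy-residual-sum outlier test calibrated by
    parametric simulation with an exclusion-and-refit workflow, cross-trait
    pleiotropy tabulation with Bonferroni thresholds, and a generator of
    synthetic GWAS summary statistics under a known causal diagram so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
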