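# mrpleio

Two-sample multivariable Mendelian randomization (MR) from GWAS summary
statistics, with pleiotropy diagnostics. The package is built for analyses
like lipid and metabolic syndrome traits in coronary artery disease, where
many instruments act on several correlated exposures at once: it selects
and LD-clumps instruments, harmonizes alleles across traits, fits
univariable and multivariable MR, quantifies heterogeneity, screens for
outlier instruments with direct outcome effects, tabulates cross-trait
pleiotropy, and ships a synthetic GWAS generator so the whole workflow runs
and is tested without any external data.

## The model

For SNP *j* with effects *β<sub>jk</sub>* on exposures *k = 1…K* and *b<sub>j</sub>* on a
binary outcome (log-OR), the working model is

```
b_j = Σ_k β_jk θ_k + α_j + ε_j,   ε_j ~ N(0, σ²_yj)
```

* **Multivariable MR-IVW** — weighted least squares of *b* on *B* with no
  intercept (α ≡ 0), weights 1/σ²<sub>yj</sub>; each θ<sub>k</sub> is the causal log-OR per
  unit of exposure *k* holding the other modeled exposures fixed.
* **Multivariable MR-Egger** — the same regression with a free intercept
  after orienting all SNPs to a positive effect on the exposure of
  interest; the intercept estimates average directional pleiotropy ᾱ.
* **Wald ratio** — single-instrument estimate *b/β* with an outcome-only
  first-order CI.
* **Heterogeneity** — Cochran's Q with the fit's weights, multivariable
  H² = Q/df and I² = max(0, (Q−df)/Q)·100.
* **Outlier screen** — leave-one-out residual-sum test calibrated by
  parametric simulation, with Bonferroni-adjusted per-SNP p-values and an
  exclusion-and-refit workflow.

## Worked example

A single-variant monogenic MR, the classic sanity check: a variant with a
per-allele CAD odds ratio of 0.90 (95% CI 0.86–0.95) and a per-allele
HDL-C effect of 0.236 SD gives, per SD of HDL-C:

```r
library(mrpleio)
by   <- log(0.90)                                  # per-allele log-OR
se_y <- (log(0.95) - log(0.86)) / (2 * 1.96)       # from the printed CI
wald_ratio(by, se_y, bx = 0.2361, exposure = "HDL")[,
  c("exposure", "or", "ci_low", "ci_high", "pvalue")]
#>   exposure        or    ci_low   ci_high       pvalue
#> 1      HDL 0.6400213 0.5183875 0.7901952 3.329806e-05
```

i.e. OR 0.64 (0.52–0.79) per SD HDL-C — a protective association driven by
this one locus.

The full synthetic study is a three-script workflow:

```sh
Rscript analysis/01_simulate.R          # build the synthetic GWAS datasets
Rscript analysis/02_run_pipeline.R      # instruments -> pleiotropy -> MR -> outliers -> loci
Rscript analysis/03_simulation_studies.R  # estimator calibration studies
```

Stage 2 prints, among other tables, the six-trait multivariable IVW on the
simulated data (true ORs 1.48, 0.87, 1.17, 1.33, 1.07, 1.037):

```
== six-trait multivariable MR (outliers excluded) ==
  exposure        or    ci_low   ci_high        pvalue i2 significant
1      LDL 1.4837767 1.4634963 1.5043382 7.967134e-239  0        TRUE
2      HDL 0.8741576 0.8605304 0.8880006  6.279771e-52  0        TRUE
3       TG 1.1717883 1.1554520 1.1883556  1.913956e-79  0        TRUE
4      BMI 1.3265612 1.3072449 1.3461630 1.957865e-159  0        TRUE
5      T2D 1.0764469 1.0606013 1.0925292  7.158527e-21  0        TRUE
6      SBP 1.0473403 1.0324357 1.0624600  5.010121e-10  0        TRUE
```

In the three-lipid model the outlier screen flags nine SNPs — the planted
direct-effect outlier that sits in the lipid panel plus eight SNPs whose
unmodeled metabolic-trait effects masquerade as direct effects; the
six-trait model absorbs those and flags exactly the three planted
outliers. Each `analysis/` script states what it found and writes its
tables under `results/`.

Key functions if you want to compose the steps yourself:
`read_sumstats()`, `select_genome_wide()`, `clump()`, `harmonize()`,
`orient_to_exposure()`, `ivw_multivariable()`, `egger_table()`,
`cochran_q()`, `presso_test()`, `exclude_and_refit()`,
`pleiotropy_crosstab()`, `restricted_set_filter()`, `simulate_sumstats()`,
`run_full_analysis()`.

## Layout

```
R/                    package code (all computation lives here)
analysis/             numbered narrative drivers over the package
scripts/acceptance.R  headline-quantity reproduction
tests/testthat/       unit, property, and acceptance test suites
vignettes/            methods vignette (models, choices, limitations)
```
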