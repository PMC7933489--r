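---
title: "Multivariable MR with pleiotropy diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariable MR with pleiotropy diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpleio)
```

# The model

Two-sample summary-statistics Mendelian randomization treats genetic
variants as instruments for one or more exposures. For SNP $j$ and exposures
$k = 1, \dots, K$, let $\beta_{jk}$ be the SNP's effect on exposure $k$
(from an exposure GWAS) and $b_j$ its effect on a binary outcome on the
log-odds-ratio scale (from an independent outcome GWAS, so the two sampling
errors are independent). The working model is

$$ b_j \;=\; \sum_k \beta_{jk}\,\theta_k \;+\; \alpha_j \;+\;
   \varepsilon_j, \qquad \varepsilon_j \sim N(0, \sigma_{y,j}^2), $$

where $\theta_k$ is the causal effect of exposure $k$ per unit change
(log-OR per SD for standardized traits, per log-OR for a binary exposure,
per mmHg for untransformed blood pressure), $\alpha_j$ is a *direct*
(exposure-independent, pleiotropic) effect, and $\sigma_{y,j}$ is the
reported standard error of $b_j$.

* **Multivariable IVW** (`ivw_multivariable()`) assumes $\alpha_j = 0$ and
  estimates $\theta$ by weighted least squares of $b$ on the $J \times K$
  matrix $B$ with no intercept and weights $w_j = 1/\sigma_{y,j}^2$.
* **Multivariable Egger** (`egger_multivariable()`) frees the intercept.
  After orienting every SNP to a positive effect on the exposure of
  interest (`orient_to_exposure()`), the intercept estimates the average
  directional pleiotropy $\bar\alpha$ and the slope is the
  pleiotropy-adjusted causal effect. Orientation is part of the estimator:
  the intercept is not sign-invariant, so a per-exposure table
  (`egger_table()`) re-orients and refits once per exposure.
* **Wald ratio** (`wald_ratio()`): with a single instrument,
  $\hat\theta = b/\beta$.

Estimates are reported as odds ratios per unit exposure with 95% CIs
($e^{\hat\theta \pm 1.96\,\mathrm{se}}$).

# Inference choices

Whether summary-statistics MR fits should use fixed-effect or
overdispersed standard errors, and a normal or t reference distribution, is
genuinely open in the literature; both are implemented and the defaults
are:

* **Multiplicative random-effects scaling** (default): coefficient SEs are
  inflated by $\max\{1, \sqrt{\mathrm{RSS}_w / (J - p)}\}$, so between-SNP
  heterogeneity widens intervals but can never shrink them below the
  fixed-effect ones. `se_scaling = "fixed"` switches this off.
* **t reference distribution** on the residual degrees of freedom
  ($J - K$, or $J - K - 1$ with an intercept), matching Egger-regression
  practice; at hundreds of instruments the difference from the normal is
  negligible.
* **Wald-ratio CI** propagates outcome uncertainty only:
  $(\,e^{(b - 1.96\sigma_y)/\beta},\; e^{(b + 1.96\sigma_y)/\beta}\,)$ with
  endpoints reordered when $\beta < 0$, and the p-value equals the
  outcome-association p. This first-order interval reproduces published
  single-variant monogenic results from their printed per-allele inputs to
  within rounding. A delta-method variant that also propagates exposure
  uncertainty is available via the `se_x` argument.

# Heterogeneity

`cochran_q()` computes the weighted residual sum of squares
$Q = \sum_j w_j (b_j - \hat b_j)^2$ with the same weights as the fit, the
multivariable $H^2 = Q/\mathrm{df}$ with $\mathrm{df} = J - p$, and
$I^2 = \max\{0, (Q - \mathrm{df})/Q\} \cdot 100$, the percent of variation
in per-SNP estimates attributable to heterogeneity beyond sampling error.
The cited multivariable $H^2$ has variants (which df, which weights); the
$Q/(J-p)$ form with fit weights is this package's documented choice.
$I^2$ is mapped onto three labels using the conventional 25/50/75 reference
values — $[0,25)$ low, $[25,75)$ moderate, $[75,100)$ high — with a
"moderate to high" annotation on $[50,75)$, since the reference scale has
four anchors but three labels are reported.

# The outlier test

`presso_test()` implements a pleiotropy-residual-sum outlier test. For each
SNP the multivariable IVW model is fitted on the panel *excluding* that SNP
and the SNP's weighted squared leave-one-out residual is recorded; the
global statistic is their sum. The null distribution comes from parametric
simulation: outcome effects are redrawn from
$N(B_j\hat\theta_{(-j)}, \sigma_{y,j})$ with exposure effects held fixed
(exposure measurement error is second-order at genome-wide-significant
instruments), and the statistic recomputed `n_sim` times. Implementation
notes:

* Leave-one-out residuals use the exact weighted hat-matrix identity
  $e_{(-j)} = e_j / (1 - h_j)$, making the whole simulation
  $O(J \cdot n_\mathrm{sim})$.
* Both the global and the per-SNP p-values use add-one smoothing
  $(1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(1 + n_\mathrm{sim})$, keeping
  them strictly positive; per-SNP p-values are then Bonferroni-multiplied
  by $J$ and capped at 1. A consequence worth knowing: the smallest
  attainable adjusted p is $J/(n_\mathrm{sim}+1)$, so flagging at
  $\alpha = 0.05$ requires $n_\mathrm{sim} > J/0.05$. The library default
  `n_sim = 1000` suits small panels; the analysis drivers use 15,000 for
  ~600-instrument panels.
* The test is exactly reproducible given `seed`, and `exclude_and_refit()`
  returns with- and without-exclusion IVW/Egger tables side by side. The
  companion distortion test and iterated exclusion are out of scope.

# Instrument selection

`select_genome_wide()` uses $p < 10^{-8}$ by default (strict inequality),
one order stricter than the conventional $5\times10^{-8}$ to account for
low-frequency variants and dense imputation. `clump()` is greedy: take the
remaining SNP with the smallest p (ties: position, then rsid), remove every
remaining SNP on the same chromosome within the window whose $r^2$ with it
exceeds the threshold (defaults $r^2 > 0.01$, $\pm 10$ Mb). "Within a 10 Mb
interval" is read as a radius around the index SNP — the kb-window
semantics of standard clumping tools — and is configurable; pairs absent
from the LD matrix count as unlinked ($r^2=0$, with a warning), which
permits sparse LD inputs. `locus_window()` keeps SNPs within a closed
$\pm 1$ Mb interval of a gene's transcription start site for monogenic MR.

# Harmonization

`harmonize()` intersects all traits' variants, keeps complete cases across
all $K+1$ traits, and aligns every trait to the first exposure's effect
allele, flipping the beta sign and replacing eaf by $1-$eaf where alleles
are swapped; strand flips (complement alleles) are recognized. Palindromic
A/T and C/G SNPs cannot be disambiguated by labels: by default they are
dropped when any trait's effect-allele frequency is missing or in
$[0.42, 0.58]$, and otherwise aligned by matching which allele is the minor
one. The underlying studies rarely state their palindromic policy; this
default is an explicit choice, switchable via `drop_palindromic` and
`ambiguous_eaf`. All drop reasons (missing, palindromic, incompatible) are
counted on the returned panel.

# The synthetic-data generator

`simulate_sumstats()` draws a complete two-sample study under the causal
diagram above: a sparse instrument-strength matrix $\gamma$ (each SNP has
one primary exposure, magnitude $\gamma_{\min} + |N(0, s_\gamma)|$ so that
instruments clear genome-wide significance at the configured exposure GWAS
size), a configurable fraction of SNPs with a cross-trait effect on a
second exposure (emulating the observed genetic overlap between lipid and
metabolic traits), direct outcome effects with configurable fraction, mean
(directional pleiotropy) and point-mass outliers, allele frequencies
uniform on $[0.05, 0.5]$, and standard errors scaling as
$1/\sqrt{2f(1-f)n}$ (times $1/\sqrt{\phi(1-\phi)}$ for the binary outcome
with case fraction $\phi$). The default sample sizes mirror a large
lipids-in-CAD study: exposure GWAS $n \approx 292{,}000$, outcome GWAS
$n \approx 547{,}000$ with case fraction 0.224, $J = 343$ instruments,
$K = 3$ exposures, 30% cross-trait pleiotropy.

`simulate_ld_blocks()` emits the matching block-diagonal $r^2$ fixture
(constant or AR-decay within blocks, zero across), with blocks laid out
across the 22 autosomes so that within-block pairs fall inside the clumping
window and distinct blocks outside it.

What the generator deliberately does **not** emulate: effect-size
correlation induced by LD (LD enters only through the clumping fixture),
individual-level binary-outcome sampling (effects are drawn directly on the
log-OR scale, the regime in which IVW/Egger are defined), sample overlap
between exposure and outcome GWAS, winner's-curse selection bias, and
realistic genome-wide LD maps. Passing recovery tests therefore demonstrate
correctness of the estimators under their own model, not robustness to
those real-data features.

# Study conditions used by the checks

The simulation suites use sizes chosen to give informative Monte-Carlo
resolution:

* IVW recovery and coverage: $J = 300$, $K = 3$,
  $\theta = (0.44, -0.15, 0.21)$, minimum instrument effect 0.15 SD at an
  exposure GWAS of $n = 10^6$, 200 replicates. With weaker instruments the
  classical regression-dilution attenuation (order
  $\sigma_x^2/\mathrm{var}(\gamma)$) becomes resolvable at this replicate
  count; the strong-instrument condition isolates the estimator's own
  behavior.
* Egger intercept recovery: constant direct effect $\alpha = 0.01$ on every
  SNP, instrument effects on the oriented exposure all positive (so
  orientation flips no rows and the intercept estimand is exactly
  $\alpha$), exposure effects measured essentially without error
  ($n_\mathrm{exp} = 10^8$) to separate the pleiotropy estimand from
  dilution. Under these conditions the Egger slope recovers $\theta$ while
  IVW is biased upward by the directional pleiotropy.
* Outlier test: type-I error at $J = 60$, $K = 3$, `n_sim = 500`, 200
  replicates under the exact regression null; power at a single SNP
  displaced by $10\,\sigma_y$, `n_sim = 2000`, 50 replicates.
* Clumping: 20-SNP block fixtures checked against a brute-force restatement
  of the greedy rule.

# Degenerate inputs and tie-breaks

Single-instrument panels reduce IVW to the Wald ratio; $J \le p$ raises an
insufficient-instruments error; collinear exposure columns are reported by
name; `bonferroni_threshold()` requires $m \ge 1$; clumping ties on p are
broken by position then rsid so results are deterministic; zero exposure
betas are left unchanged by orientation; $Q = \mathrm{df}$ maps to
$I^2 = 0$ (truncation at zero).

# Limitations

Correlated instruments are not modeled in the regressions (clumping is
assumed to have removed LD; a generalized IVW for correlated SNPs is out of
scope), weighted-median/mode and Steiger-filtered estimators are not
provided, and the outlier test's simulation redraws only the outcome side.
The pipeline de-duplicates instruments by rsid across trait sets when
pooling for multivariable models; locus assignment beyond rsid identity is
not attempted.
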