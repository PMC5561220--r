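---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Mendelian randomization treats genetic variants as instrumental variables.
For SNP $j$, let $\gamma_j$ be its per-allele effect on the exposure and
$\Gamma_j$ its effect on the outcome, estimated in two non-overlapping
samples with standard errors $\sigma_{\gamma j}$ and $\sigma_{\Gamma j}$.
If the SNP affects the outcome only through the exposure (the exclusion
restriction), then $\Gamma_j = \theta\,\gamma_j$ for the causal effect
$\theta$, and each SNP supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{\Gamma j} / |\hat\gamma_j|$ (the exposure-side uncertainty
is ignored, the usual convention when instruments are strong; the
F-statistics below quantify "strong").

A valid instrument must (i) associate with the exposure, (ii) share no
confounder with the outcome, and (iii) satisfy the exclusion restriction.
Violations of (iii) — pleiotropy — are the central worry, and the
estimator suite exists to triangulate against them:

* **IVW.** The precision-weighted mean of the ratios,
  $\hat\theta = \sum_j w_j\hat\beta_j / \sum_j w_j$ with
  $w_j = \hat\beta_j$'s inverse squared SE; fixed-effects SE
  $(\sum_j w_j)^{-1/2}$. The multiplicative random-effects model scales
  that SE by $\max(1, \hat\phi)$ where
  $\hat\phi^2 = \sum_j w_j(\hat\beta_j - \hat\theta)^2/(J-1)$:
  heterogeneity can widen the interval but never narrow it. The `auto`
  rule uses fixed effects with three or fewer SNPs (too few to estimate
  dispersion) and random effects with four or more, re-applied per
  analysis variant after exclusions. Unbiased only if pleiotropy is absent
  or balanced.
* **Correlated instruments.** When instruments are in linkage
  disequilibrium their outcome-effect sampling errors are correlated and
  plain IVW overstates precision. `mr_ivw_correlated()` is the
  generalized least-squares regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin with covariance
  $\Omega_{jk} = \sigma_{\Gamma j}\sigma_{\Gamma k}\rho_{jk}$ built from
  the *signed* LD matrix; $\hat\theta = (\gamma'\Omega^{-1}\gamma)^{-1}
  \gamma'\Omega^{-1}\Gamma$, SE $(\gamma'\Omega^{-1}\gamma)^{-1/2}$.
* **Weighted median.** The estimate at the 50th percentile of the
  weight-ordered ratios, found by linear interpolation of the cumulative
  weight midpoints; consistent as long as valid instruments carry more
  than half the total weight, i.e. up to 50% of SNPs may be invalid. Its
  SE comes from a parametric bootstrap (redraw each $\hat\gamma_j$,
  $\hat\Gamma_j$ from normals with the reported SEs).
* **MR-Egger.** Weighted regression
  $\hat\Gamma_j = \beta_0 + \theta\,\hat\gamma_j$ with weights
  $\sigma_{\Gamma j}^{-2}$, each SNP first oriented so
  $\hat\gamma_j \ge 0$. The slope estimates $\theta$ even when *all*
  instruments are pleiotropic, provided instrument strength is
  independent of the direct effects (InSIDE); the intercept estimates
  the average directional pleiotropic effect, and its p-value is the
  directional-pleiotropy test.

p-values use a normal reference for IVW and the weighted median and a
$t_{J-2}$ reference for Egger; confidence intervals are
$\hat\theta \pm 1.96\,\mathrm{SE}$ throughout. These are conventional
choices; the literature is not unanimous, and with very few SNPs all of
them are optimistic.

## Instrument construction

`ld_prune()` implements greedy pruning: SNPs are visited by ascending
p-value (ties broken lexicographically by rsID, so runs are
deterministic) and kept only if their squared correlation with every
already-kept SNP is below the threshold (default r² = 0.8). Greedy
best-p-first — rather than, say, maximum-independent-set search — is the
standard field practice and is reproducible; the suite verifies the
output is maximal (every discarded SNP conflicts with a kept one).

`apply_proxies()` substitutes, for each instrument absent from the
outcome study, its highest-r² available proxy at or above the r²
threshold (default 0.8); instruments with no eligible proxy are dropped
and logged. If a `proxy_stats` table supplies the proxy's own published
association, that row replaces the original wholesale; otherwise only
the rsID changes and the original effect is retained — at r² ≥ 0.8 the
two differ by little, and no attenuation correction is applied.

`f_statistic()` uses the variance-standardized-trait approximation
$R^2 = 2p(1-p)\beta^2$, $F = R^2(n-2)/(1-R^2)$, which needs only the
effect-allele frequency, effect size and sample size. **It assumes the
trait is in SD-comparable units**; for unstandardized effects divide
$\beta$ by the trait SD first. $F < 10$ is flagged as weak by the usual
convention.

## Harmonization

Two consortia rarely report the same effect allele. For every shared SNP
the outcome record is aligned to the exposure orientation: matched
alleles are kept; swapped alleles flip the sign of $\hat\Gamma_j$ and
replace eaf by 1 − eaf; strand-complemented records (A↔T, C↔G per
allele) are complemented first. Palindromic SNPs (A/T or C/G pairs) are
invisible to letter matching, so a policy decides:

* `frequency` (default): align by which side of 0.5 the effect-allele
  frequencies fall on; exclude the SNP as ambiguous when both
  frequencies are within `eaf_window` (default 0.08) of 0.5. The window
  default is a compromise — wide enough that modest frequency noise
  between two European-ancestry panels cannot silently flip an allele,
  narrow enough not to discard most palindromes.
* `drop`: exclude all palindromic SNPs (safest, loses data).
* `keep`: assume both studies report the same strand (defensible when
  both are on the same imputation panel).

Irreconcilable allele pairs (e.g. A/C vs A/G) are excluded with a
recorded reason, never a fatal error; every exclusion appears in the
`excluded` attribute and, in pipeline runs, the audit file. Matching is
by exact rsID only — positional matching would need coordinates, which
the summary format does not carry.

## The synthetic generator

`simulate_two_sample()` draws true exposure effects
$\gamma_j \sim U(0.05, 0.3)$ and frequencies $p_j \sim U(0.1, 0.5)$, sets
$\sigma_{\gamma j} = (2p_j(1-p_j)n_{\mathrm{exp}})^{-1/2}$ (and
analogously for the outcome sample), builds
$\Gamma_j = \theta\gamma_j + \alpha_j$ with the direct effects
$\alpha_j$ following the configured pleiotropy law, and adds normal
sampling noise with those SEs — correlated within LD blocks through the
Cholesky factor of the block correlation, *independently in the two
samples*, since two-sample designs share no subjects and therefore no
sampling noise, only LD structure. Direct effects are drawn
independently of $\gamma_j$, so InSIDE holds by construction. The SE
model ties instrument strength to sample size the way real GWAS do,
which makes the F-statistic module meaningful on simulated data.

Scenario defaults are fixed study conditions, not tuning knobs: 20
instruments and GWAS sizes of 50 000 for the generic scenarios;
`directional` uses mean direct effect 0.05 (about a sixth of the
smallest $\theta\gamma_j$ — visible but not dominant);
`thirty-percent-invalid` gives 6 of 20 SNPs a direct effect of 0.1,
large enough that a ratio-averaging estimator is visibly biased while
valid instruments still hold a weight majority; `correlated-blocks` uses
four blocks of five SNPs at r = 0.5, past the pipeline's LD trigger but
far from singular; `paper-shaped` mimics an inflammatory-marker analysis
— null effect, exposure n = 200 000, three skeletal-site outcome samples
of 8 000, 32 000 and 28 000.

What the generator does *not* emulate: winner's-curse selection of
genome-wide-significant SNPs, allele-frequency mismatch between samples,
population stratification, sample overlap, and non-normal effect
distributions. Passing tests therefore demonstrate correctness of the
estimators under their own assumptions, not robustness of MR to these
real-data pathologies.

## Numerical choices

* The GLS solve uses a Cholesky factorization and triangular solves,
  never an explicit inverse; if $\Omega$'s exact condition number
  exceeds $10^{12}$ a ridge of $10^{-10}$ is added to the diagonal and a
  message emitted. This keeps near-duplicate instruments
  ($\rho \to 1$) from double counting while failing loudly on a truly
  non-positive-definite input.
* LD matrices must be symmetric within $10^{-10}$ (averaged), have unit
  diagonal, entries in $[-1, 1]$, and minimum eigenvalue above
  $-10^{-8}$.
* The weighted median interpolates linearly between the two ratios
  bracketing cumulative weight 0.5 and clamps to the extreme ratios when
  0.5 falls outside the midpoint range (possible when one SNP carries
  most of the weight).
* The Egger SE uses the unscaled $(X'WX)^{-1}$ from the QR
  decomposition multiplied by $\max(1, \hat\sigma)$, so exactly
  collinear toy data yield the exact slope and intercept with zero SE
  rather than 0/0.
* Random-effects inflation is floored at 1: underdispersion never
  shrinks an interval. A side effect, quantified by the suite, is a
  mildly conservative test under the exact null (true size ≈ 0.95% at a
  nominal 1.25% with 20 SNPs).
* Summary tables are written with 17 significant digits and read with
  the base-R (strtod) parser, so read–write cycles reproduce every
  numeric field exactly.

## Design decisions

* **Origin-constrained GLS by default.** For correlated instruments the
  intercept-free regression is the default; `intercept = TRUE` adds an
  Egger-style free intercept under the same $\Omega$ weighting, exposed
  but flagged experimental. The weighted median has no accepted
  correlated-instrument form, so an attached LD matrix is a hard error
  there (an NA row in pipeline reports).
* **LD trigger.** After pruning, the pipeline switches IVW to the GLS
  form when any remaining off-diagonal $|r|$ exceeds `ld_r_threshold`
  (default 0.1); below that the correlation correction is smaller than
  Monte-Carlo noise in any realistic report.
* **Significance threshold.** `alpha` defaults to 0.05 divided by the
  number of exposures, the Bonferroni-style rule for screening several
  candidate exposures (0.0125 when four markers are tested); it is
  recomputed from the config, not hard-coded.
* **Reproducibility.** Seeds are mandatory in simulation and analysis
  configs. The weighted-median bootstrap seed is derived per
  exposure × outcome cell, so the all-SNPs and excluded variants of the
  same cell use identical bootstrap draws and differ only through the
  exclusion list — an invariant the suite asserts.
* **NA rows, not missing rows.** Estimators infeasible on a cell (WM
  and Egger need more than two SNPs) produce NA rows, keeping report
  shape stable for downstream tabulation.

## Problem sizes in the test suite

The statistical checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted bands: 500 replicates for parameter-recovery
and robustness means, 2000 for the type-I error rate, 100 random
instances for the GLS/IVW equivalence, and single large draws (2000–5000
SNPs) for the generator's noise-calibration invariants, which is
statistically equivalent to many small replicates. Bootstrap SEs inside
the recovery loops use small `n_boot` since only point estimates enter
those assertions; the user-facing default stays at 2000.

## Known limitations

* No MR-PRESSO, mode-based, multivariable MR, or Steiger filtering; no
  individual-level (2SLS) analysis.
* Proxy handling substitutes rsIDs (optionally full associations) but
  never corrects effect sizes for $r^2 < 1$ attenuation.
* The F-statistic formula assumes standardized traits; applying it to
  unstandardized effects inflates R².
* Harmonization cannot rescue palindromic SNPs whose frequencies sit
  near 0.5 in both samples; they are excluded by design under the
  default policy.
* With three or four instruments the weighted median and Egger are
  formally feasible but fragile; treat their intervals with caution.
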