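# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, as a
tidyverse-native R package.

MR uses genetic variants as instrumental variables: because alleles are
assigned at random at conception, a SNP that raises an exposure (say,
circulating C-reactive protein) can stand in for a randomized nudge to that
exposure, giving causal-effect estimates that are not confounded by
lifestyle or reverse causation. In the *two-sample* design the SNP–exposure
effects (γ̂ⱼ, σ_γⱼ) and SNP–outcome effects (Γ̂ⱼ, σ_Γⱼ) come from different
study samples — e.g. an inflammatory-marker GWAS and a bone-mineral-density
consortium — so only published summary statistics are needed.

`mrpipe` implements the full analysis path:

- **Instrument construction** — greedy LD pruning at a configurable r²
  threshold (keeping the smallest p-values), proxy-SNP substitution for
  instruments missing from the outcome study, pleiotropy-flag exclusion for
  sensitivity analyses, and per-SNP instrument strength
  (R² = 2p(1−p)β², F = R²(n−2)/(1−R²)).
- **Harmonization** — expressing both samples' effects on the same effect
  allele, resolving allele swaps and strand flips, with a
  frequency/drop/keep policy for palindromic (A/T, C/G) SNPs.
- **Estimators** — per-SNP Wald ratios Γ̂ⱼ/γ̂ⱼ (SE σ_Γⱼ/|γ̂ⱼ|);
  inverse-variance weighted (IVW) meta-analysis with fixed or
  multiplicative random effects (auto rule: fixed for ≤ 3 SNPs, random for
  ≥ 4); an LD-aware generalized least-squares IVW for correlated
  instruments, θ̂ = (γᵀΩ⁻¹γ)⁻¹γᵀΩ⁻¹Γ with Ωⱼₖ = σ_Γⱼσ_Γₖρⱼₖ; the weighted
  median (consistent with up to 50% invalid instruments) with
  parametric-bootstrap SEs; and MR-Egger regression, whose intercept
  estimates average directional pleiotropy.
- **Synthetic data** — a two-sample summary-statistic generator with known
  causal effect, configurable pleiotropy (balanced / directional / partial)
  and block LD, so the whole pipeline is testable without downloading
  consortium data.
- **Reporting** — a tidy report table (one row per
  exposure × outcome × variant × method), per-SNP audit trail, funnel- and
  scatter-plot data plus ggplot2 helpers.

## Worked example

Simulate an hsCRP-like instrument set (20 SNPs, exposure n = 200 000)
against three bone-density outcome samples with no true causal effect, and
run the full design:

```r
library(mrpipe)

sim <- simulate_two_sample(scenario("paper-shaped", seed = 7))
cfg <- mr_config(
  exposures = list(list(name = "hsCRP_like", data = sim$exposure)),
  outcomes  = lapply(names(sim$outcomes), function(nm)
    list(name = nm, data = sim$outcomes[[nm]])),
  alpha = 0.0125, seed = 7)
report <- run_mr_analysis(cfg)
dplyr::select(tidy(report), outcome, variant, method, n_snps, estimate, se, pvalue)
#> # A tibble: 18 × 7
#>   outcome      variant  method   n_snps estimate     se pvalue
#>   <chr>        <chr>    <chr>     <int>    <dbl>  <dbl>  <dbl>
#> 1 forearm      all      IVW          20   0.0308 0.0230  0.180
#> 2 forearm      all      WM           20   0.0357 0.0307  0.245
#> 3 forearm      all      MR-Egger     20  -0.0234 0.0482  0.633
#> 4 forearm      excluded IVW          20   0.0308 0.0230  0.180
#> ...
```

Eighteen rows = 1 exposure × 3 outcomes × 3 methods × 2 analysis variants
(all SNPs, and excluding flagged pleiotropic SNPs — identical here because
no SNP is flagged). No p-value beats the multiple-testing threshold
α = 0.0125, as expected under a null simulation: the IVW estimate at the
forearm, 0.031 (SE 0.023, p = 0.18), is sampling noise around zero on the
SD-of-outcome scale.

Single estimates print compactly:

```r
h <- harmonize(sim$exposure, sim$outcomes$forearm)
mr_ivw(h)
#> IVW estimate (20 SNPs, random effects)
#>   beta = 0.0308  se = 0.0230  95% CI [-0.0142, 0.0759]  p = 0.18
f_statistic(sim$exposure)
#> # A tibble: 20 × 4
#>   rsid        r2 f_statistic weak
#>   <chr>    <dbl>       <dbl> <lgl>
#> 1 rs1001 0.0397        8272. FALSE
#> 2 rs1002 0.00790      1592.  FALSE
#> ...
```

All fitted objects support broom-style `tidy()`/`glance()`, and
`plot_funnel()`, `plot_scatter()` and `autoplot()` on reports give the
standard MR diagnostics.

Real summary statistics enter through `read_summary_table()` (tab-delimited
with a `column_map` for nonstandard headers), `read_ld_matrix()` (signed r,
not r²), `read_proxy_table()` and `read_flags_table()`.

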