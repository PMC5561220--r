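Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian
    randomization with GWAS summary statistics. Covers instrument
    construction (LD pruning, proxy substitution, pleiotropy-flag
    exclusion, F-statistics), allele harmonization between exposure and
    outcome samples, and a suite of causal-effect estimators: per-SNP Wald
    ratios, inverse-variance weighted meta-analysis (fixed and
    multiplicative random effects, with an LD-aware generalized
    least-squares variant for correlated instruments), the weighted-median
    estimator with parametric-bootstrap standard errors, and MR-Egger
    regression with its directional-pleiotropy intercept test. A synthetic
    two-sample summary-statistic generator with known ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
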