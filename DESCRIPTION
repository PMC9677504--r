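Package: momr
Title: Multi-Omics Mendelian Randomization with Dependence-Aware P-Value Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates GWAS and multi-omics QTL summary statistics in a
    two-sample Mendelian randomization framework. Provides per-exposure causal
    effect estimators (inverse-variance weighted, generalized least squares
    under linkage disequilibrium, SMR, GSMR, multivariable MR), gene-level
    combination tests for dependent P-values (Cauchy combination, harmonic
    mean P-value, minimum P, Fisher with chi-squared or gamma calibration
    using the covariance of GLS z-statistics), LD clumping, and a simulation
    benchmark of empirical type I error and power under horizontal and
    vertical pleiotropy with configurable sample overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
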