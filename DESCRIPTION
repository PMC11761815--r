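Package: metamixg
Title: Mixture-Model Meta-Analysis of the Standardized Mean Difference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-effects meta-analysis of Hedges' g reformulated as a
    mixture model. Provides exact marginal moments (mean, variance, third
    central moment, skewness) of g at the study and meta-analysis level,
    unbiased method-of-moments estimators of the mean true effect and the
    between-study (specific) variance tau-squared, mixture-model study-level
    variances for inverse-variance weighting, DerSimonian-Laird and REML
    comparators, and a Monte Carlo plus nonparametric-bootstrap evaluation
    harness. All user-facing functions take data frames of per-study records
    and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
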