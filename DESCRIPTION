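Package: mipool
Title: Pooling Smooth-Term Significance Tests After Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Combines per-imputation significance tests of smooth covariate
    effects (penalized-spline generalized additive models and cubic B-spline
    regressions) into a single pooled p-value by the median p-value rule, the
    mean p-value rule, the Cauchy combination test, and two variants of the
    D2 statistic-pooling rule. Includes the simulation machinery needed to
    study these rules: a Friedman-type benchmark data generator with normal
    or binary outcomes, multivariate amputation under MCAR, MAR and MNAR
    mechanisms, and multiple imputation by chained equations with
    predictive-mean-matching and random-forest column imputers, together
    with a Monte-Carlo harness that estimates power and type-I error of
    every pooling rule against full-data and complete-case benchmarks.
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
    mgcv,
    parallel,
    purrr,
    ranger,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
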