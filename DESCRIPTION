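Package: factorinfer
Title: Simultaneous Inference for Factor Loadings in High-Dimensional
    Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simultaneous hypothesis tests for entries of the loading
    matrix in approximate factor models with observed factors. Provides
    max-type test statistics (studentized and non-studentized) with
    multiplier-bootstrap critical values, an extreme-value benchmark test,
    a step-down procedure with strong family-wise error rate control,
    Bonferroni-Holm and Benjamini-Hochberg comparators, synthetic panel
    generators with sparse-precision or equicorrelated error structure,
    and Monte-Carlo drivers for size, power and multiple-testing
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
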