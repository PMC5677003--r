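Package: serialdep
Title: Serial Dependence and Working-Memory Noise Models for Delayed-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for trial-history (serial-dependence) effects in
    spatial delayed-response tasks. Provides a seeded synthetic session
    generator, trial-level preprocessing (origin and outlier filters, circular
    LOESS removal of stimulus-dependent systematic error, history annotation),
    derivative-of-Gaussian and Clifford tuning-curve fitting with a signed
    peak-to-peak statistic, permutation and bootstrap inference, a power-law
    fit of response variance against memory delay, and maximum-likelihood
    fitting with AICc comparison of equal-precision, variable-precision, and
    von-Mises-random-walk noise models with serial-dependence and swap
    extensions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
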