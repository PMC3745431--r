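Package: interpower
Title: Power and Type 1 Error Tradeoffs for Interaction Tests in Linear
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo and closed-form power calculations for two-way
    interaction (moderation) tests in ordinary least squares regression with
    a continuous outcome.  Simulates standard-normal predictors, optionally
    median-split into 0/1 indicators, fits the product-term model, and
    estimates empirical power over a grid of sample sizes, standardized
    interaction effect sizes and Type 1 error rates.  A noncentral-t
    analytic engine serves as an independent cross-check, and scenarios are
    classified by whether elevating the Type 1 error rate from 5% to 20%
    yields a useful gain in power (a relative increase of at least 10% with
    at least 80% power at the elevated rate).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
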