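Package: jishuku
Title: Stigma, Habituation and Voluntary Self-Restraint Under Repeated
    Emergency Declarations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models voluntary going-out restraint ('jishuku') under repeated
    non-punitive emergency declarations. Implements a stigma model of the
    going-out decision with a habituation discount on the stigma cost,
    computes its fixed-point equilibria, the self-restraint effect and its
    comparative statics in the number of declarations; generates synthetic
    prefecture-by-day mobility panels with the Japanese emergency-declaration
    schedule, weather-like covariates and disturbances carrying unit effects,
    spatial autocorrelation and AR(1) serial correlation; and estimates
    within fixed-effects regressions with cluster-robust covariance as well
    as the spatial-error random-effects model with AR(1) errors by maximum
    likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
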