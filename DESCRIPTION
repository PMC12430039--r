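Package: sleepdmpm
Title: Dynamic Multivariate Panel Models and Interventional Contrasts for Sleep-Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian modelling of three daily sleep-quality outcomes
    (binary daytime sleepiness and ordinal ease of falling asleep / ease of
    waking up) from short diary panels, with cross-lagged dependence between
    outcomes and 35 covariates in six factor categories (stress, bedtime
    conditions, weather, physical attributes, exercise habits, dietary
    habits).  Provides a synthetic diary-panel generator with known ground
    truth, a Hamiltonian Monte Carlo fitter with convergence diagnostics,
    and interquartile do-intervention contrasts that rank factor categories
    by their posterior-predictive effect on each outcome, summarised as
    tidy tables and forest-style plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
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
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
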