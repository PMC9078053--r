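Package: crowdpool
Title: Population Pooling Models of Visual Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting of weighted population-pooling models of
    visual crowding in orientation-matching tasks, with a rival noise-only
    model. Provides Gaussian-tuned population responses with smooth early and
    late noise, weighted target/flanker pooling, maximum-readout decisions,
    circular response-error histograms, simulation-based least-squares fitting
    (coarse grid search followed by Nelder-Mead refinement under common random
    numbers) and AIC model comparison. Includes a synthetic-cohort generator
    emulating adult-periphery, typically developing, and amblyopic observers,
    and a tailored QUEST staircase simulator for acuity and crowding-extent
    measurement against 4AFC psychometric observers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
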