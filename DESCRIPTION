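Package: treadgait
Title: Forward-Dynamics Simulation of Treadmill Versus Overground Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sagittal-plane forward-dynamics simulation of human walking on
    overground surfaces and on speed-controlled treadmills.  Provides a
    seven-segment floating-base biped with penalty foot-ground contact, a
    treadmill belt driven by a saturated zero-order-hold PD speed controller
    (plus an ideal kinematic-belt mode), a reference-tracking gait controller
    scored by motion-imitation rewards, a synthetic periodic reference-gait
    generator, and an analysis stage that segments gait cycles and quantifies
    per-joint maximum and RMS kinematic differences across grids of maximum
    belt force, belt control frequency, body mass and walking speed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
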