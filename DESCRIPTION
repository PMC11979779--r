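Package: canopyoptim
Title: Optimality-Based Modelling of Forest Photosynthesis and Transpiration
    Under Nitrogen and Water Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily stand-level gross primary production and canopy
    transpiration for boreal conifer forests, computed from joint optimization
    of stomatal conductance and leaf nitrogen concentration against a
    hydraulic-risk cost and nitrogen-maintenance costs.  Couples a co-limited
    Farquhar-type leaf photosynthesis model with delayed seasonal temperature
    acclimation, a soil-plant hydraulics model (Brooks-Corey retention, sigmoid
    xylem vulnerability, fixed-point canopy water-potential solver), a
    two-segment diurnal scheme, big-leaf canopy upscaling, a seeded synthetic
    weather generator, and Laplace-likelihood calibration with differential
    evolution, repeated holdout validation, and ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
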