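Package: crossfeed
Title: Kinetic Modeling and Calibration of Cross-Feeding Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and calibrates Monod-type kinetic models of small
    microbial consortia growing in batch culture on a single carbohydrate
    substrate, with acid (acetate, lactate) production, product inhibition,
    acid cross-feeding as secondary substrates, and pairwise biomass-scaled
    interaction parameters. Includes an adaptive Runge-Kutta ODE core,
    a synthetic-data generator emulating microplate and bioreactor batch
    designs, staged parameter estimation by scatter search (mono-culture
    first, then paired co-culture interaction terms), practical
    identifiability via parameter correlation matrices, Monte-Carlo local
    sensitivity analysis, and in-silico bacteriostatic knockout experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
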