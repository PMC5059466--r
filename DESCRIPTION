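Package: atnsim
Title: Dynamic Allometric Trophic Network Simulation
Version: 0.1.0
Authors@R: person("ATN", "Maintainers", email = "maintainers@atnsim.org",
    role = c("aut", "cre"))
Description: Simulates body-mass-structured plant-animal communities on a
    dynamic two-nutrient base. Species are defined by body mass alone:
    feeding links follow a Ricker success curve around an optimal
    consumer-resource mass ratio, feeding rates use a multi-prey
    Beddington-DeAngelis functional response with a variable Hill exponent,
    and metabolic, growth and capture rates scale allometrically.
    Communities are integrated to stationarity with an extinction threshold,
    community-level ecosystem functions (biomass stocks, herbivory,
    intraguild predation, metabolic losses) are extracted over an evaluation
    window, and their scaling with initial animal richness is summarised by
    log-log power-law fits.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
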