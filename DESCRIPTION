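Package: syntmfa
Title: Thermodynamics-Based Metabolic Flux Analysis for Syntrophic Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thermodynamics-based metabolic flux analysis (TMFA)
    of constraint-based metabolic models: mixed-integer formulations coupling
    reaction directionality to transformed Gibbs energies with
    confidence-interval uncertainty, parsimonious (minimum total flux) TMFA,
    thermodynamic variability analysis of fluxes, energies and metabolite
    concentrations, and a fixed-biomass chemostat formulation for two-species
    syntrophic cocultures. Ships curated core models of the propionate-oxidizing
    bacterium Syntrophobacter fumaroxidans and the hydrogenotrophic methanogen
    Methanospirillum hungatei, together with condition profiles, maintenance
    and uptake-rate calibration routines, and seed-reproducible synthetic
    network generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    Matrix,
    jsonlite,
    xml2,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Python (>= 3.9) with numpy and scipy (>= 1.9) on PATH
    (MILP backend, scipy.optimize.milp/HiGHS)
Config/testthat/edition: 3
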