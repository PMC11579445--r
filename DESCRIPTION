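Package: crowndynamics
Title: Individual-Tree Demography from Repeat Airborne Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the height growth, crown expansion, dieback and mortality
    of individual trees across repeat airborne laser scanning surveys of open
    woodland. Detects and delineates tree crowns on canopy height models with
    a two-stage, allometry-constrained region-growing segmentation, matches
    crowns between surveys by centroid containment, classifies tree fate with
    a relative-decline rule, converts crown dimensions to stem diameter and
    aboveground biomass through published allometries, computes topographic
    wetness and neighbourhood-competition covariates, fits generalised
    additive models of demographic rates, and aggregates rates and canopy
    structural change onto a one-hectare landscape grid. Includes a synthetic
    woodland-scene generator with known ground truth so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
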