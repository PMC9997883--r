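Package: actevolve
Title: Evolutionary Optimisation of Cell Migration in the Act Cellular Potts Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of T-cell migration behaviour in a
    two-dimensional Act cellular Potts model (CPM), where motility emerges
    from a positive feedback on recently protruded lattice sites. Provides
    the CPM engine with adhesion, volume, perimeter and protrusion-activity
    energies, construction of empty and densely packed "skin" (keratinocyte)
    environments, a mu+lambda genetic algorithm over the two motility
    parameters (max_act, lambda_act) with an area-exploration fitness,
    track statistics (step-based speeds, weighted mean squared displacement
    with two-stage Fuerth fitting, autocovariance persistence times), a
    constraint-free run-and-pause reference model of T-cell migration, and
    synthetic-data generators with known ground truth for validating every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
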