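Package: lineagenoise
Title: Noise Decomposition for Stochastic Gene Expression in Growing Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based analysis of stochastic biochemical kinetics in
    growing and dividing cell populations. Computes the population growth
    rate and age structure from an interdivision-time distribution
    (Euler-Lotka equation), solves age-resolved linear-noise-approximation
    moment equations subject to cell-division boundary conditions by a
    shooting method, and decomposes gene-expression variability into
    intrinsic, transmitted cell-cycle and cell-age components for both
    population snapshots and isolated lineages (mother-machine setting).
    Includes closed forms for a bursty two-reporter model, an exact
    algebraic solution for linear reaction networks, feedback-strength
    sweeps, and an exact event-driven agent-based simulator of lineage
    trees with dual reporters for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
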