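Package: pcabm
Title: Stochastic On-Lattice Agent-Based Model of the Prostate Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the prostate tumor microenvironment as a stochastic
    cellular automaton on a bounded 2-D lattice, with tumor cells (androgen
    sensitive and castration resistant), fibroblasts, and M1/M2 polarized
    macrophages as agents under androgen-proficient (R1881) or
    androgen-deprived (DMSO vehicle) parameter regimes. Ships calibrated
    parameter presets for both hormone conditions, a catalog of co-culture
    scenarios (monocultures, tumor-fibroblast, tumor-fibroblast-macrophage,
    and castration-resistance seedings), growth-curve normalization and
    fold-change reporting, a nearest-neighbor clustering index for resistant
    foci, particle swarm optimization for calibrating model probabilities to
    growth-curve data with a staged replicate-aware protocol, and generators
    for synthetic growth-curve datasets matching the structure of live-cell
    imaging experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
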