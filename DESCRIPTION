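Package: mtnetsim
Title: Agent-Based Simulation and State Classification of Microtubule-Motor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates active networks of growing microtubules and two-headed
    crosslinking motors (KIF11-like, plus-end directed) in a thin periodic
    slab, including a piecewise-linear steric/depletion pair force,
    worm-like-chain bending, tubulin-limited plus-end growth, and
    force-velocity motor kinetics with distinct side and end unbinding.
    Provides the network-state quantification pipeline built on seven
    descriptors (windowed nematic order, crosslink taxonomy P/AP/X/End,
    minus-end mobility, largest-cluster fraction) and a PCA plus K-means
    classifier that assigns simulated networks to aster, parallel-bundle,
    extensile-bundle or gliding-mesh organizational states, together with
    synthetic fixture generators with analytically known descriptor values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
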