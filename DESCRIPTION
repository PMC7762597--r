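Package: polychan
Title: Lattice Monte Carlo Simulation of Block Copolymers in Tight Nanochannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of a coarse-grained two-block
    linear copolymer on a simple cubic lattice, confined to a long nanochannel
    with impenetrable walls and periodic ends. Implements the classical
    Verdier-Stockmayer move set (kink-jump, crankshaft, end moves, reptation),
    phantom-chain conformational entropy by the statistical counting method,
    Helmholtz free-energy and force/impulse analysis, mean squared displacement
    (autocorrelation) curves for the chain mass centre and individual beads,
    anomalous-diffusion exponent estimation with automatic scaling-regime
    segmentation, and block-swap event statistics. Includes exhaustive
    self-avoiding-walk enumeration oracles for validating the sampler against
    exact Boltzmann distributions on tiny systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    mclust,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
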