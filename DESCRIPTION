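Package: DomainCoupling
Title: Domain-Domain Coupling Analysis for ABC Transporters from HDX-MS
    Kinetics, Equilibrium Stability and Trajectory Correlation Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of inter-domain coupling in multidomain
    membrane transporters. Fits peptide-level hydrogen-deuterium exchange
    (HDX-MS) deuterium-uptake time courses with mono- and biexponential
    models and converts exchange-rate ratios into opening free-energy
    differences; deconvolutes EX1 bimodal isotope envelopes into
    folded-fraction time courses and derives unfolding rate constants and
    Eyring activation energies; performs two-state equilibrium stability
    analysis (urea titrations with linear extrapolation to water and to
    37 degrees C, unfolding-rate extrapolation, Boltzmann melt fits);
    and computes residue-motion generalized-correlation networks from
    coordinate trajectories, with community decomposition, betweenness
    centrality, RMSF and fraction-of-native-contacts profiles. A
    synthetic-data module generates every input type with planted
    ground-truth parameters so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports:
    stats,
    utils,
    bio3d,
    igraph,
    minpack.lm,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
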