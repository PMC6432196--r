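Package: samcpoly
Title: Flat-Histogram Monte Carlo for Sterically Stiff Square-Well Polymer Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic Approximation Monte Carlo (SAMC) estimation of the
    density of states of single fused-hard-sphere polymer chains with a
    square-well attraction, where chain stiffness is controlled sterically by
    the bond length. Provides bond-length-preserving continuum Monte Carlo
    moves, combined micro-canonical and canonical thermodynamic analysis
    (entropy derivatives, specific heat, canonical reweighting of
    energy-resolved observables, transition location and order
    classification), contact-matrix observables, knot-type identification of
    collapsed conformations via the Alexander determinant, a brute-force
    uniform-sampling oracle for small chains, and plain-text input/output for
    density-of-states tables and XYZ conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
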