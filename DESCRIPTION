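Package: fdpb
Title: Finite-Difference Poisson-Boltzmann Electrostatics for Protein-DNA
    Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuum-electrostatics toolkit for protein-nucleic-acid
    systems: whitespace-dialect PQR structure handling (charge templates,
    residue mutation, selections, rigid translations), a finite-difference
    Poisson-Boltzmann solver (successive over-relaxation, edge-based
    dielectric maps, Debye-Huckel boundary conditions, linear and nonlinear
    modes), surface-potential and electric-field-line analysis, net
    electrostatic force scans along the mass-center separation axis, and
    pH-dependent relative folding energies from titratable-site pKas.
    Deterministic synthetic structure generators emulate a net-negative DNA
    double helix with a flipped-out base and a polar enzyme with a
    positively ringed binding face, so the whole pipeline can be exercised
    and validated against analytic oracles without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
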