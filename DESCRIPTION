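Package: cgidp
Title: Coarse-Grained Simulation and Phase-Behaviour Analysis of
    Intrinsically Disordered Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-bead-per-residue implicit-solvent modelling of
    intrinsically disordered proteins. Implements the Ashbaugh-Hatch
    stickiness potential with truncated-and-shifted Debye-Hueckel
    electrostatics, Langevin dynamics for single-chain and
    direct-coexistence (slab) geometries, density-profile and interface
    analysis yielding coexisting phase concentrations, block-average
    error estimation for correlated observables, and a Bayesian
    optimizer for the residue stickiness scale that combines
    thermodynamic reweighting with a kernel-density prior built from
    hydrophobicity scales. Ships the CALVADOS 1 and CALVADOS 2
    residue parameter tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
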