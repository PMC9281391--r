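Package: dgap
Title: Delta-Learning Gaussian Approximation Potentials for Molecular Co-Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and validating delta-machine-learned
    interatomic potentials for multi-component molecular crystals. A fast,
    long-ranged physical baseline calculator is corrected by short-ranged
    sparse Gaussian-process models on SOAP (smooth overlap of atomic
    positions) descriptors, split into per-component intramolecular
    corrections and a single intermolecular correction. Includes periodic
    structure handling with molecule perception, extended-XYZ and CIF input,
    farthest-point-sampling data selection, energy/force/virial training,
    variable-cell relaxation, constant-pressure molecular dynamics, and the
    crystal-structure-prediction evaluation metrics (lattice energies,
    density deviations, RMSD15, force statistics), together with an analytic
    toy universe for end-to-end validation of the delta-learning workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
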