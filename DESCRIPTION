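Package: elcv
Title: Energy Landscape Exploration and Heat Capacity Analysis for Peptide Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring potential energy landscapes of coarse-grained
    peptide models and analysing their thermodynamics. Provides differentiable
    toy potentials (Mueller-Brown surface, Lennard-Jones clusters, a bead-chain
    peptide model), basin-hopping and basin-hopping parallel tempering with
    Cartesian, group-rotation and rigid-body dimer move sets, transition-state
    location by doubly nudged elastic band seeding and hybrid
    eigenvector-following refinement, stationary-point databases in the
    min.data/ts.data flat-text convention, harmonic superposition heat
    capacities with detection and decomposition of low-temperature features,
    disconnectivity graphs with superbasin analysis, conformational descriptors
    (end-to-end distance, four-site signed dihedral), and synthetic multi-funnel
    landscape generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
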