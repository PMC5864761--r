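Package: dualbind
Title: Dual Binding Modes of Cohesin-Dockerin Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the dual binding modes of cohesin-dockerin
    complexes. Derives the symmetry axis relating the two binding
    orientations from a pair of crystal structures, generates rigid-body
    (Z, phi) pose grids with steric masking, and aggregates per-pose
    free-energy landscapes into Boltzmann-weighted mode free energies and
    mode probabilities. Also implements a structure-based (Go-type)
    C-alpha coarse-grained model with native contacts defined by an
    atomic overlap criterion, Langevin dynamics with a fifth-order
    predictor-corrector integrator, and protocols for thermal stability,
    thermal unfolding, and constant-speed (AFM-like) stretching with
    force-extension analysis. Synthetic generators for landscapes and
    toy helical structures make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
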