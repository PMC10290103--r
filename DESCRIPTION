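Package: epizern
Title: Electrostatic and Shape Complementarity of Protein Interfaces via
    2D Zernike Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies electrostatic and shape complementarity at
    protein-protein interfaces. Spherical surface patches cut from
    solvent-accessible molecular surfaces (DMS point clouds carrying
    Poisson-Boltzmann potentials sampled from OpenDX grids) are projected
    onto their best-fit plane as 25x25 matrices: an electrostatic matrix
    (EM), its sign-simplified (SEM) and capped (CEM) variants, and a shape
    matrix of distances to a 45-degree cone origin. Complementarity is
    scored either as the F sign-concordance fraction between paired SEMs
    or as the Euclidean distance between rotation-invariant 2D Zernike
    descriptors of the projections, and evaluated against random decoy
    patches with ROC/AUC, stratified by pH, binding affinity and dimer
    class. A synthetic-complex generator with known ground-truth
    complementarity makes the full pipeline testable without external
    structure or solver runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
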