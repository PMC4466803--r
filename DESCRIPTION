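Package: beakfem
Title: Finite-Element Analysis of Bite Loading in Darwin's Finch Beaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for comparative beak biomechanics in
    Darwin's finches. Converts jaw-muscle dissection data (bundle mass and
    fiber length) into physiological cross-sectional areas and the jugal and
    palatine load vectors acting on the upper beak, generates parametric
    two-material (bone core plus keratin rhamphotheca) tetrahedral beak
    meshes for the four functional beak types, solves the small-strain
    linear-elastic problem with four-node tetrahedra under tip- and
    base-biting constraints, and post-processes solutions into regional
    98th-percentile von Mises stresses, model bite forces, engineering
    safety factors, and shape-versus-safety Pearson correlations with
    Bonferroni control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
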