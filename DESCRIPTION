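Package: kneefem
Title: Finite Element Contact Modelling of the Mouse Knee from Micro-CT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for subject-specific finite element contact
    analysis of the murine tibiofemoral joint. Generates parametric knee-like
    micro-CT phantoms with known ground truth, reconstructs bone and cartilage
    geometry by Gaussian smoothing, single-level thresholding, landmark rigid
    registration and Boolean mask algebra, fills the soft meniscus by a
    morphological gap wrap, converts multi-tissue label volumes to conforming
    linear tetrahedral meshes, and solves displacement-controlled small-strain
    elasticity with kinematic coupling, tied interfaces and finite-sliding
    frictionless penalty contact. Post-processing reports per-condyle contact
    pressure statistics at a matched reaction force and compares individual,
    individual-with-meniscus and generic homogeneous cartilage model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
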