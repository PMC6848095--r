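Package: spinerod
Title: Elastic Rod Mechanics of the Sagittal Spinal Profile and Scoliotic 3D Deformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the adolescent spine as a slender, initially curved elastic
    rod and asks whether the shape of the sagittal (side-view) profile alone
    predisposes it to three-dimensional scoliosis-like deformation. Generates
    synthetic S-shaped sagittal profiles with prescribed kyphotic/lordotic
    segment structure, deforms them with a geometrically nonlinear corotational
    beam finite-element solver under per-vertebral-level gravitational loading
    plus a small axial torque, and quantifies the resulting centerline shapes:
    global geometric (Frenet) torsion, loop versus lemniscate axial projection,
    twist counts, directional displacement ratios, k-means subtype clustering,
    and pairwise deformation-pattern correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    withr
Config/testthat/edition: 3
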