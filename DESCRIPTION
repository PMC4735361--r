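Package: csdwave
Title: Cortical Spreading Depression Waves on Triangulated Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cortical spreading depression as a modified
    Rogers-McCulloch firing-rate reaction-diffusion system on closed
    triangulated surface meshes, discretised with P1 surface finite
    elements (Laplace-Beltrami cotangent stiffness, consistent or lumped
    mass) and an implicit-explicit time stepper solved by preconditioned
    conjugate gradients. Provides an all-sources simulation protocol over
    a per-vertex region atlas, activation-time matrices, asymmetry and
    retention indices, activation-time versus centroid-distance datasets,
    and robust outlier detection of regions via the minimum covariance
    determinant estimator. Includes synthetic geometry generators
    (icosphere, flat sheet, bent duct) and plain-text mesh and atlas I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    MASS,
    withr
Config/testthat/edition: 3
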