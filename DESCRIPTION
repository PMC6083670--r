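Package: mwihead
Title: Microwave Scattering Forward Models of a Human Head for Brain Stroke Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling toolkit for differential microwave head imaging.
    Builds voxel head phantoms (synthetic layered ellipsoids or Zubal-style raw
    label grids), assigns frequency-dispersive dielectric properties through
    fourth-order Cole-Cole and Debye relaxation models with a 60-to-21 tissue
    mapping, emulates haemorrhagic and ischaemic strokes as spherical dielectric
    anomalies, and solves the frequency-domain scalar Helmholtz scattering
    problem (2D finite elements, coarse 3D finite differences) with perfectly
    matched layers, an elliptical multi-static dipole array, hand-written
    GMRES/FGMRES/BiCGStab Krylov solvers with ILU(0) preconditioning, mesh
    convergence and solver benchmarking protocols, electric-field-norm
    differential stroke localization, and specific absorption rate safety
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    pracma,
    yaml,
    stats,
    utils,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
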