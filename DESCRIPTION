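Package: corneamech
Title: Two-Scale Mechanical Model of the Human Cornea and Keratoconus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-to-continuum mechanics of a planar slice of human
    corneal stroma under intraocular pressure. Implements a finite-kinematics
    spring-lattice model of collagen lamellae connected by proteoglycan
    crosslinks (radial and diagonal struts), solved by Newton continuation
    with an analytic sparse tangent, together with the rigorously upscaled
    anisotropic hyperelastic continuum (four fibre families in a polar
    frame) solved by total-potential minimisation on a structured bilinear
    finite-element grid. Includes a localized stiffness-damage model of
    keratoconus, shape and stress metrics (apex displacement, central
    thickness, interface curvature), convergence and parameter-sweep
    studies, and CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
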