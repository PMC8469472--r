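Package: odontometry
Title: Automated Digital Odontometry on Triangulated Tooth Crowns
Version: 0.1.0
Authors@R: person("ADO", "Maintainers", email = "ado@example.org", role = c("aut", "cre"))
Description: Fully automated morphometric analysis of 3D tooth crown
    reconstructions. Reads, repairs and writes triangulated surfaces
    (PLY, STL, OBJ), estimates principal and Gaussian curvature, detects
    the occlusal border as a high-curvature loop, derives an anatomical
    tooth coordinate system (vertical, mesio-distal, vestibulo-oral axes),
    slices the crown into a dense stack of parallel transverse contours,
    detects cusp-tip / occlusal landmarks on each contour in Euclidean or
    curvature mode, splits enamel-cap contours at the cervical enamel
    edges, and aggregates per-section odontometric parameters into
    enamel-dentine comparative reports. Includes a parametric two-cusp
    synthetic tooth generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
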