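Package: segvis3d
Title: Semi-Supervised Lesion Segmentation and Realistic Volume Rendering of 3D Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for visual analysis of lesions (meningioma and surrounding
    FLAIR hyperintensity) in 3D medical images. Implements a semi-supervised
    3D segmentation pipeline built around probability-aware weighted random
    cropping and an uncertainty-rectified pyramid-consistency objective on a
    V-Net style deep-supervision network, together with a physically based
    Monte Carlo volume renderer (null-scattering path tracing with a macrocell
    majorant grid and 3D-DDA traversal) whose two-dimensional transfer
    function includes an importance dimension that highlights segmented
    regions. A synthetic brain phantom generator makes the whole pipeline
    testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
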