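Package: kerato3d
Title: Keratoconus Detection from Frontal and Lateral Eye Images via 3D
    Corneal Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated keratoconus screening and staging from a pair of 2D eye
    photographs (one frontal, one lateral). The frontal view is searched for
    the iris with a circular Hough transform; scale-invariant keypoints link
    the two views; corneal depth is measured from the lateral profile with a
    right-triangle construction anchored on the limbus chord; the two
    orthogonal views are fused by a translational transform into a 3D corneal
    surface; severity is graded from the steepest corneal slope (mild below 45
    degrees, moderate from 45 to 52, severe above 52) and, optionally, by a 3D
    convolutional neural network over reconstructed corneal volumes. A
    parametric eye-phantom generator with analytically known geometry makes
    every stage testable end to end, and an evaluation toolkit provides
    confusion matrices, accuracy/sensitivity/specificity, stratified k-fold
    cross-validation, Pearson correlation and Bland-Altman agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
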