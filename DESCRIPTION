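Package: chiasmseg
Title: Optic Chiasm Segmentation and Malformation Detection from T1w MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting malformed optic chiasms from T1-weighted MRI
    volumes via the failure of a control-trained segmenter. Implements an
    intensity-percentile algorithm that corrects noisy atlas-derived chiasm
    masks, a 3D U-Net (native C++ forward/backward with soft-Dice loss and
    Adam training), joint image/mask augmentation (normalization, random
    flip, crop and b-spline affine), slice-restricted Dice evaluation with
    normality-gated two-sample testing under Bonferroni familywise
    correction, and a polynomial-kernel C-SVC read-out on the Dice feature.
    A seeded synthetic phantom generator provides X-shaped chiasm volumes
    with ground-truth and corrupted atlas-like masks, including malformed
    variants with narrowed chiasm/nerves and widened tract angle, so the
    whole pipeline runs without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
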