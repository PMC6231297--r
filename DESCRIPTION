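Package: mci25d
Title: Predicting MCI-to-AD Conversion from Hippocampal 2.5D Patches
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting conversion from mild cognitive
    impairment (MCI) to Alzheimer's disease (AD) from structural MRI in a
    common template space. Volumes are intensity-normalized by histogram
    matching and corrected for normal aging with a per-voxel linear model;
    2.5D tri-planar 32x32x3 patches are sampled inside a hippocampus mask
    under fixed spacing constraints; a small convolutional neural network
    trained on AD versus normal-control patches supplies deep features for
    MCI subjects; principal component analysis and least-angle-regression
    LASSO reduce and select deep and structural features, which a kernel
    extreme learning machine classifies under leave-one-out or k-fold
    cross-validation. Includes a synthetic brain-phantom cohort generator
    with group-dependent hippocampal atrophy, a linear age trend and
    additive noise, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
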