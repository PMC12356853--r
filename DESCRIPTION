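Package: fcdmaps
Title: Voxel-Based Detection of Focal Cortical Dysplasia from Normative
    Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric detection of focal cortical dysplasia (FCD) type II
    on T1-weighted MRI. Computes junction (gray-white matter blurring),
    extension (gray-matter density), and cortical-thickness feature maps from
    a three-class tissue segmentation, scores patients voxel-wise against
    normative mean/SD templates built from control cohorts (optionally
    age-adjusted), extracts suprathreshold clusters, detects post-resection
    cavities from co-registered pre/post-operative pairs, and evaluates
    detections against reference masks with DICE, percent overlay, and
    voxel-level ROC/AUC. Ships a seeded synthetic head-phantom generator with
    ground-truth lesions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
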