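Package: resectr
Title: Automated Resection-Cavity Segmentation and Remnant Volumetry for
    Postsurgical Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments surgical resection cavities on postoperative
    T1-weighted brain MRI using an ensemble of three 2D encoder-decoder
    networks applied along the axial, coronal and sagittal planes, fused by
    per-voxel majority vote and cleaned by connected-component filtering and
    a detection-size screen. Includes NIfTI volume input/output with
    orientation canonicalization, a synthetic brain-phantom generator with
    known ground-truth cavities and a toy parcellation, subject-level
    cross-validation utilities, segmentation evaluation metrics (Dice,
    95th-percentile Hausdorff distance, volume agreement, detection
    outcomes), and atlas-intersection remnant volumetry reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
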