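Package: thalavol
Title: Thalamus Segmentation Evaluation and Volumetry Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking automated thalamus (deep grey matter)
    segmentation methods against a reference segmentation and for relating
    the resulting volumes to clinical outcomes. Covers NIfTI mask handling
    and label-scheme extraction, quantitative-map intensity harmonization
    and mutual-information registration quality control, multi-contrast
    majority-vote label fusion, voxel-wise agreement metrics (Dice,
    precision, sensitivity, containment), volumetric concordance statistics
    (Lin's concordance correlation coefficient, ICC(3,1), calibration
    regression, Bland-Altman bias analysis), covariate-adjusted
    cross-sectional and longitudinal clinical association models with
    HC3 robust errors and Benjamini-Hochberg correction, and a synthetic
    phantom cohort generator with known injected parameters so every
    pipeline stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    sandwich,
    lmtest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
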