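Package: petstand
Title: Post-Acquisition Intensity Standardization of PET Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-acquisition intensity standardization for activity
    concentration (AC) and standardized uptake value (SUV) positron emission
    tomography (PET) volumes. A one-time calibration step estimates a standard
    intensity scale from a cohort of normal scans with a reference-organ mask:
    an optimal upper percentile beta is chosen to minimize the coefficient of
    variation of the reference-organ mean across the cohort, the standard
    median landmark is the cohort mean of linearly mapped body medians, and an
    inverse scale factor restores physical intensity meaning. A per-image
    transformation step then maps each scan onto the standard scale by a
    piecewise-linear landmark mapping, with no segmentation required beyond
    automatic body-region thresholding. The package also provides Gaussian,
    Z-score and simplified histogram-landmark baseline normalizers, cohort
    evaluation statistics (coefficient of variation of organ means,
    repeat-scan mean absolute difference, inter-scanner group comparison), a
    synthetic body-torso phantom cohort generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
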