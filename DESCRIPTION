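Package: nethom
Title: Network Homogeneity Analysis of Resting-State fMRI with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for network-homogeneity (NH) analysis of the
    default-mode network in resting-state fMRI: seeded two-group synthetic BOLD
    cohort simulation with known ground truth, volume discarding and motion
    screening, nuisance regression with global signal preserved, linear
    detrending with ideal band-pass filtering, Gaussian spatial smoothing,
    group spatial independent component analysis with template-based
    default-mode component selection, per-voxel network homogeneity with Fisher
    z and subject-level standardization, voxel-wise two-sample t comparison
    with Gaussian random field cluster-level correction, cluster reporting
    with peak world coordinates, clinical correlation and demographics
    statistics, and RBF-kernel support vector machine classification of
    cluster-mean features with grid search and cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
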