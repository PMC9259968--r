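Package: perafr
Title: Percent Amplitude of Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxelwise amplitude analysis of resting-state BOLD
    fMRI. Computes percent amplitude of fluctuation (PerAF) together with
    ALFF and fALFF, performs temporal preprocessing (initial volume discard,
    motion-based subject exclusion, white-matter and ventricle nuisance
    regression, linear detrending), contrasts two groups with voxelwise
    two-sample t-maps and Monte-Carlo (AlphaSim-style) cluster-extent
    correction, and evaluates regional amplitude as a diagnostic marker via
    ROC curves and a leave-one-out linear SVM with a permutation null.
    Includes a synthetic BOLD cohort generator with planted regional
    amplitude effects so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    pROC,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
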