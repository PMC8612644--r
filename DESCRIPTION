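Package: facetopo
Title: Multi-Level MVPA and Topography of Category Representations in fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multi-level multivariate
    pattern analysis (MVPA) of event-related fMRI. Generates event-related
    designs and voxel data with planted, spatially offset category signals;
    estimates per-run condition responses by GLM; computes split-data
    representational similarity matrices, the category discriminability
    index, and Kendall tau model correlations with FDR-controlled group
    inference; performs pairwise linear-SVM decoding with leave-one-run-out
    cross-validation; maps pattern statistics over the volume with
    fixed-size searchlight neighborhoods; quantifies the spatial separation
    of peak-activation distributions (rank tests, ANOSIM, explicit-parameter
    Gaussian-mixture AIC comparison, Dice overlap); and derives seed-based
    winner-take-all functional connectivity parcellations. A low-level
    visual control module provides image spectrum and histogram
    equalization, Gabor simple/complex feature extraction, and multiclass
    leave-one-sample-out classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    e1071,
    Matrix,
    RNifti,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
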