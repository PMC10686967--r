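Package: alesim
Title: Simulation-Based Validation of Activation Likelihood Estimation for
    Voxel-Based Morphometry Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the behaviour of coordinate-based meta-analysis by
    activation likelihood estimation (ALE) when applied to structural
    (voxel-based morphometry) neuroimaging data. Provides quantile-anchored
    samplers emulating the parameter distributions of the BrainMap VBM
    database (subject and foci counts), simulation of coordinate datasets
    with an injected ground-truth effect on a masked brain grid, a full ALE
    implementation with voxel-level and cluster-level family-wise-error
    permutation inference, and outcome measures (sensitivity, spurious
    convergence rate, and dominant-experiment contribution fractions) used
    to derive minimum dataset-size recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
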