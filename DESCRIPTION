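Package: petnorm
Title: Voxel-Wise Normative Modelling of PET Parametric Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Normative modelling of molecular-imaging parametric maps
    (e.g. dopamine-synthesis Ki or receptor-density BPND) across
    multi-scanner cohorts. Provides empirical-Bayes (ComBat) and
    Gaussian-smoothing scanner harmonization, voxel-wise Bayesian
    linear regression normative models with cross-validated deviation
    (Z) maps, extreme-deviation analytics (per-subject summaries,
    group overlap maps, risk ratios), rank-based and permutation
    inference with threshold-free cluster enhancement, clinical
    correlation, and ROC/DeLong treatment-response classification,
    together with a multi-site cohort simulator and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
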