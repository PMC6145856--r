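Package: docprog
Title: Multidomain Prognostic Modelling for Chronic Disorders of Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates single-subject prognostic models for chronic
    disorders of consciousness from resting-state fMRI functional-network
    features and clinical characteristics. Implements the full analysis chain:
    synthetic cohort and BOLD data generation with planted network structure,
    motion-aware preprocessing (volume censoring by framewise displacement,
    nuisance regression, band-pass filtering), pairwise functional-connectivity
    and template-resemblance feature construction, two-stage feature selection
    (univariate correlation filter followed by competitive adaptive reweighted
    sampling with partial least squares regression), PLS regression of the
    one-year CRS-R outcome with significant-multivariate-correlation predictor
    importance and an ROC-derived classification cutoff, plus internal
    validation by optimism-corrected bootstrap, out-of-bag voting, permutation
    tests, Bland-Altman agreement, and single-domain versus multidomain model
    comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
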