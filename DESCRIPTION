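Package: docgini
Title: Spectral Gini Indices for EEG Depth-of-Consciousness Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hypnotic depth of general anesthesia from
    single-channel EEG using inequality measures on the power spectrum: the
    spectral Gini index (SpG) and its thresholded, low-complexity variant, the
    binarized spectral Gini index (BSpG). Ships the standard comparator
    indices (spectral entropy, permutation entropy, approximate entropy,
    detrended fluctuation analysis exponent, and bispectral SynchFastSlow),
    an epoching and smoothing pipeline, a three-compartment propofol
    pharmacokinetic simulator with effect-site link and sigmoid Emax
    pharmacodynamic fitting, prediction-probability and rank-correlation
    evaluation statistics, and a seeded synthetic anesthesia-EEG generator
    so the full analysis can be exercised without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
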