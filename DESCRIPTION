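Package: neurocardiac
Title: Heart Rate Variability and Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking cardiac autonomic regulation to
    resting-state functional brain connectivity. Detects heartbeats from
    finger-pulse recordings and computes time- and window-resolved heart
    rate variability (SDNN, RMSSD); builds physiological-noise regressors
    (respiratory-phase Fourier terms, respiration volume per time with
    delayed copies) and cleans 4-D BOLD images by nuisance regression,
    band-pass filtering and Gaussian smoothing; maps seed-based
    connectivity with Fisher-z transformed correlations and sliding-window
    dynamic connectivity coupled to windowed SDNN; and compares whole-brain
    connectomes on spherical parcels with a network-based statistic using
    permutation family-wise error control. A synthetic-data generator
    produces pulse, respiration and BOLD inputs with known ground truth so
    every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
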