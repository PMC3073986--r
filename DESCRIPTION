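Package: inforate
Title: Information Transfer Rate Estimation for Continuous Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the rate of information transfer (bits per second)
    between two simultaneously sampled continuous signals, assuming only
    stationarity and ergodicity. Mutual information between delay-embedded,
    delay-aligned and PCA-reduced signal blocks is estimated with a
    Kraskov-type k-nearest-neighbour estimator, and the information rate is
    read off as the slope of mutual information versus embedding dimension.
    Includes the cross mutual information function for latency detection, a
    filtered-Gaussian-channel simulator with an analytic coherence-based
    capacity oracle for validation, and preprocessing utilities for gappy,
    oversampled sensor time series (shape-preserving cubic interpolation,
    Kaiser-window anti-aliasing decimation, sliding windows).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
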