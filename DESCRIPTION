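Package: bgmci
Title: Causal Discovery for ROI BOLD Time Series with Momentary Conditional Independence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage time-series causal discovery (PCMCI-style) for region-of-interest
    BOLD signals, as used to map functional interactions of the human basal-ganglia
    motor circuit. Provides the signal-conditioning chain (nuisance regression,
    high-pass filtering, per-subject normalization, block concatenation with edge
    smoothing), three conditional-independence tests (linear partial correlation,
    Gaussian-process regression with distance correlation, and k-nearest-neighbor
    conditional mutual information), block-shuffle permutation significance that
    respects temporal autocorrelation, a link taxonomy (instantaneous versus delayed,
    linear versus non-linear versus complex, permanent versus task-dependent), and a
    synthetic multichannel generator with known ground-truth causal graphs for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
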