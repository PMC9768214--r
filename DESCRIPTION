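Package: plinet
Title: Phase-Lag-Index Functional Brain Networks from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds functional brain networks from multichannel EEG by
    phase lag index (PLI) connectivity on Hilbert instantaneous phase,
    thresholds them into binary graphs over a proportional sparsity grid,
    and computes small-world graph metrics (clustering, characteristic
    path length, gamma, lambda, sigma, global and nodal local efficiency)
    normalized against degree-preserving rewired reference networks.
    Includes a synthetic-EEG generator with controllable per-band,
    per-region phase coupling emulating six evoked mental states
    (resting, fatigue, attentive, inattentive, positive, negative), ROI
    aggregation on a 30-channel 10-20 montage, subjective-scale state
    labeling, and two-sample t-test / Cohen's d group comparisons, so the
    whole analysis chain runs end-to-end on simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
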