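Package: calspike
Title: Cross-Modality Reconciliation of Electrophysiology and Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Observatory", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconciling visual response metrics measured with
    extracellular electrophysiology (spike trains) and two-photon calcium
    imaging (dF/F fluorescence). Simulates matched stimulus tables and tuned
    spiking populations, transforms spikes into synthetic 30 Hz fluorescence
    via a Hill-nonlinearity calcium forward model, extracts calcium events by
    exact L0-penalized changepoint detection with noise-calibrated sparsity
    and by non-negative deconvolution, computes responsiveness, selectivity
    (lifetime sparseness, gOSI) and preference metrics identically for both
    modalities, quantifies cross-modality discrepancies with Jensen-Shannon
    distances and bootstrap nulls, and reduces them via quantile
    sub-selection, laminar and running-fraction matching, and Gaussian
    mixture clustering of response reliabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
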