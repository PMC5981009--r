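Package: connmix
Title: Mixture-Model Thresholding of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparsifies functional connectivity matrices by modeling the
    distribution of Fisher-transformed partial correlations as a two-component
    mixture of a pseudo-null (Gaussian or Laplace) and a positive signal
    component (Gamma or Inverse-Gamma), fitted by expectation-maximization,
    and thresholding at a user-chosen pseudo false discovery rate. Includes
    partial-correlation estimation from regional BOLD time series via
    empirical or Ledoit-Wolf (constant-correlation target) shrinkage precision
    matrices, competing thresholding schemes (hard, proportional, and
    permutation-based edge-wise nulls at the group or subject level), a
    synthetic BOLD benchmark generator with known ground-truth network
    structure (linear neural dynamics driving balloon-Windkessel
    haemodynamics), and evaluation utilities (performance, ROC/AUC, FDR
    calibration, index of overlap, intraclass correlation, group contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
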