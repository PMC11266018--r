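Package: cvte
Title: Complex-Valued Transfer Entropy for Directed Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates directed (causal) connectivity between pairs of
    complex-valued time series, such as magnitude and phase signals from
    complex-valued fMRI, using a complex-valued transfer entropy that
    combines magnitude-magnitude and phase-phase transfer entropy with
    partial transfer entropy cross terms. Includes symbolic encoding of
    continuous series, a permutation-surrogate significance test for the
    direction verdict, real-valued baseline methods (symbolic and
    histogram transfer entropy, Granger causality), autoregressive
    simulation families with known ground-truth direction for
    benchmarking, and edge-wise two-group comparison of connectivity
    matrices with false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
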