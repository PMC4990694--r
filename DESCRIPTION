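Package: pnpmrf
Title: Plug-and-Play Magnetic Resonance Fingerprinting with Heterogeneous Transmit Fields
Version: 0.1.0
Authors@R:
    person("pnpmrf", "developers", email = "pnpmrf@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for plug-and-play magnetic
    resonance fingerprinting (PnP-MRF), a quantitative MRI method that
    interleaves two complementary, heterogeneous radio-frequency transmit
    fields into a fingerprinting pulse train. Provides an extended phase
    graph (EPG) signal simulator with a brute-force isochromat oracle, the
    four-segment 480-excitation sequence schedule, construction of the 4-D
    (T1, T2, per-channel B1+) fingerprint dictionary with view-sharing
    compression, exact non-uniform Fourier encoding of radially undersampled
    k-space, receive-sensitivity estimation and matched-filter combination,
    exhaustive compressed-fingerprint matching, analytic synthetic transmit
    coil fields with magnitude-least-squares shimming, and an end-to-end
    digital-phantom pipeline with recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
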