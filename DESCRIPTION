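Package: gatedfcs
Title: Time-Gated STED-FCS Analysis of TCSPC Photon Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of fluorescence correlation spectroscopy (FCS)
    measurements recorded photon-by-photon with time-correlated single
    photon counting (TCSPC), aimed at gated STED-FCS on commercial
    microscopes with pulsed excitation and a continuous-wave depletion
    laser. Provides a photon-stream data model with lifetime histograms
    and microtime gating, a multi-tau photon-mode autocorrelator with a
    brute-force oracle and segment-based error estimates, fitting of the
    one-component two-dimensional anomalous-diffusion FCS model with a
    triplet term, counts-per-molecule and observation-spot FWHM
    calibration from transit-time ratios, a multi-gate workflow that
    extracts a range of observation-spot sizes from a single measurement,
    and a Brownian-dynamics simulator of labelled lipids in a supported
    bilayer with position-dependent fluorescence lifetimes under a
    depletion doughnut, triplet blinking, photobleaching and background.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    arrow,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
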