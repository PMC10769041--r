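Package: hybridgaze
Title: Hybrid Smooth-Saccadic Control Models of Yaw Gaze Stabilization
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Models the yaw gaze stabilization reflex of flying insects as a
    switched hybrid control system: a continuous proportional-integral (PI)
    feedback loop acting on a first-order yaw plant through a sensorimotor
    transport delay, supervised by an integrate-and-fire saccadic reset that
    fires when the integrated velocity error crosses a switching threshold.
    Provides transfer-function construction with Pade delay approximants,
    pole- and Nyquist-based stability analysis (stability fields, dividing
    surfaces, gain and phase margins), a fixed-step time-domain simulator of
    the hybrid system with delay line and reset events, sum-absolute-error
    performance sweeps over gains, frequency and switching threshold, and a
    set of reproducible desk-scale experiments with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    signal,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
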