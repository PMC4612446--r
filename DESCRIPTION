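Package: scrdcm
Title: Model-Based Inference of Anticipatory Sympathetic Arousal from
    Skin Conductance Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates trial-wise anticipatory sympathetic arousal
    (amplitude, onset and duration) from continuous skin conductance
    recordings in fear-conditioning designs by inverting a constrained
    non-linear forward model in which Gaussian sudomotor bursts drive a
    third-order linear differential equation. Includes the standard
    electrodermal preprocessing chain (median despiking, Butterworth
    low-pass and configurable uni-/bi-directional high-pass filtering,
    downsampling, normalisation), canonical and individually estimated
    response functions, chunk-wise maximum-a-posteriori inversion with
    configurable trial depth, conventional peak scoring as a benchmark,
    a predictive-validity evaluation based on negative log likelihood
    and log Bayes factors, and a synthetic cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics
Suggests:
    deSolve,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
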