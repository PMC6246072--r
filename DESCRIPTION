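Package: binratio
Title: Short-Term Binaural Speech Intelligibility Modelling on Synthetic Room Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binaural speech intelligibility in multi-interferer
    scenes by combining short-time better-ear listening with an
    equalization-cancellation account of binaural unmasking. Signals are
    analysed through an ERB-spaced gammatone filterbank in 24-ms
    half-overlapping Hann frames; long-term target statistics are combined
    with short-term interferer statistics to produce a broadband effective
    target-to-interferer ratio (the "binaural ratio") whose differences
    across conditions predict speech-reception-threshold differences.
    Includes a synthetic acoustic-scene generator (image-source binaural
    room impulse responses with a spherical-head cue model, speech-shaped
    and speech-like modulated maskers, and a behind-the-ear hearing-aid
    microphone transform), interaural cue analysis (ILD, ITD, coherence),
    an adaptive 1-up-1-down staircase simulator, and an orchestrator for
    the full aided/unaided x separated/collocated x masker-type condition
    matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
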