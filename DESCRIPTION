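Package: earmod
Title: Effective Auditory Model Chains and Their Evaluation Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates monaural auditory processing with effective model
    chains built from a linear gammatone cochlea, optional broken-stick
    compression, inner-hair-cell envelope extraction (half-wave
    rectification plus lowpass cascades), auditory-nerve adaptation
    (divisive adaptation loops or highpass adaptation), and subcortical
    modulation processing (resonator modulation filter banks and the
    same-frequency inhibition-excitation CN/IC circuit).  Ships a full
    comparison battery for such chains: calibrated synthetic stimuli,
    excitation patterns, cochlear input-output curves, Q-factor
    estimation from frozen noise, filter counting, AC/DC phase-locking
    metrics, adaptation and rate-level analyses, synchrony-capture
    envelope metrics, modulation transfer functions, and click-train
    responses.  Results are returned as tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    signal,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
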