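Package: cochfat
Title: Cochlear Fatigue Metrics for Noise-Induced Hearing Loss Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models gradually developing noise-induced hearing loss as
    high-cycle mechanical fatigue of the organ of Corti. Calibrated acoustic
    pressure waveforms are passed through an external-ear gain stage and a
    middle-ear stapes-velocity transfer function, then through a triple-path
    nonlinear (TRNL) cochlear filterbank to obtain basilar-membrane velocity
    maps on an ERB-spaced tonotopic grid. From these maps the package computes
    two fatigue-based exposure metrics: the equal velocity level (EVL), an
    S-N-curve energy metric, and the complex velocity level (CVL), a Miner-rule
    metric built on rainflow cycle counting of the velocity load history. A
    noise synthesizer (Gaussian, impulsive, chirp and Gaussian-plus-impulse
    mixtures), A-weighted equivalent level computation, a packaged chinchilla
    hair-cell-loss dataset and single-variable regression utilities support
    validation of the metrics against hearing-loss indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
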