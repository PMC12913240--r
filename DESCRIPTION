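Package: lgerp
Title: Paired-Stimulus Local-Global Auditory ERP Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the paired-stimulus local-global auditory oddball
    paradigm: generation and validation of constrained stimulus schedules,
    simulation of continuous multichannel EEG carrying event-related
    potential components (P1-N1-P2 complex, mismatch negativity, P3a, P3b)
    over 1/f plus alpha background activity, a zero-phase preprocessing and
    epoching chain with matched amplitude-based artifact rejection,
    group-level cluster-based permutation statistics with threshold-free
    cluster enhancement, individual-level classification sensitivity testing
    with a dual permutation framework, and a sensor-by-epoch factorial
    degradation sweep with rank-correlation bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    signal,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
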