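Package: remosc
Title: Oscillation and Connectivity Analysis for Intracranial REM Sleep
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for characterising rhythmic activity in human
    intracranial sleep recordings. Provides feature-based REM sleep
    staging from polysomnographic channels, detection of theta and beta
    oscillations against a robustly fitted power-law (1/f) spectral
    background, amplitude-envelope burst detection, pooled multitaper
    coherence with analytic and permutation significance, and lead/lag
    analysis of band-power envelopes between brain regions. A synthetic
    recording generator with known ground truth (spectral exponents,
    burst times, coupling and envelope lags) makes every stage of the
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
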