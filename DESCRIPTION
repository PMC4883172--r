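Package: eegspike
Title: Two-Stage Detection of Interictal Epileptiform Spikes in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of interictal epileptiform discharges
    (spikes and sharp waves) in single-channel EEG. A mimetic first stage
    finds candidate transients whose two half-waves satisfy amplitude and
    duration thresholds; a second stage embeds the candidate waveforms by
    locality preserving projections (a graph-Laplacian generalized
    eigenproblem) into a space of intrinsic dimensionality estimated by
    maximum likelihood, and refines the candidates with a class-weighted
    radial-basis-function support vector machine whose kernel width is
    calibrated to a target within-kernel pair fraction. Includes
    latency-windowed scoring against expert markers, ten-fold
    cross-validation of the refinement stage, a seeded synthetic-EEG
    generator with planted spikes and distractors, EDF and delimited-text
    recording input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
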