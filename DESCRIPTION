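Package: neurokey
Title: Binary Key Generation from Multichannel Neural Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates reliable, revocable binary cryptographic keys from
    multichannel electrophysiological recordings such as intracortical local
    field potentials. Raw signals are bandpass filtered, segmented by
    behaviour, framed into trials, and summarised as log band-power features.
    A population-level Gaussian margin model then selects subject-specific
    reliable feature pairs and quantizes them into per-subject bit strings
    (key templates), which are matched at authentication time by normalized
    Hamming distance against a per-subject threshold. Includes evaluation
    metrics (authentication accuracy, false acceptance rate, min-entropy),
    a synthetic cohort simulator for end-to-end validation, and a pipeline
    for registration and evaluation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
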