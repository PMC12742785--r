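Package: fnirsae
Title: LSTM Autoencoder Anomaly Analysis for fNIRS Hemodynamic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window LSTM autoencoder analysis of multichannel
    functional near-infrared spectroscopy (fNIRS) recordings. Trains a
    sequence autoencoder on a reference task, scores other tasks by
    per-channel reconstruction error, and compares expertise groups with
    robust summaries, permutation tests, and nonparametric effect sizes.
    Includes a block-design hemodynamic cohort simulator with plantable
    group-by-task effects, readers and writers for wide CSV and a SNIRF
    subset, and an end-to-end replicated pipeline with window-size
    selection and report rendering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
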