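Package: rrafnet
Title: Atrial Fibrillation Screening from RR-Interval Sequences with a
    Compact 1D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds subject-wise windowed RR-interval datasets from
    rhythm-annotated long-term ECG recordings (WFDB beat and rhythm
    annotations), trains a compact one-dimensional convolutional neural
    network that separates atrial fibrillation from sinus rhythm on raw
    inter-beat intervals, converts the trained network to a full-integer
    INT8 representation for microcontroller deployment, evaluates folds
    with aggregated confusion matrices, and simulates the embedded
    buffer-infer-publish signal flow. A seeded synthetic cohort generator
    makes every stage runnable and testable without downloading clinical
    data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
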