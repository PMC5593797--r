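Package: cryseg
Title: Automatic Segmentation of Infant Cry Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated segmentation of newborn cry recordings into
    expiratory cries, audible inspirations, background silence and other
    acoustic activity. Frames of a recording are first classified with
    per-class Gaussian mixture models or hidden Markov models trained on
    mel-frequency cepstral features (computed from the raw spectrum or from
    a recombination of empirical-mode-decomposition intrinsic mode
    functions), then a post-processing stage refines labels and segment
    boundaries using dynamic intensity and zero-crossing-rate thresholds
    estimated from background silence together with fundamental-frequency
    evidence. Includes a seeded synthetic cry-scene generator, frame-level
    evaluation metrics and cross-validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
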