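Package: apneawave
Title: Wavelet-Packet EEG Features for Sleep Apnea Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying sleep apnea from single-channel
    polysomnography EEG. Reads recordings from European Data Format (EDF)
    files, removes powerline interference with a zero-phase notch filter,
    decomposes 30-second epochs with a wavelet packet filter bank into the
    five clinical EEG frequency bands (delta, theta, alpha, beta, gamma),
    extracts wavelet entropy, band energy and four band-power ratio indices
    (14 features per recording), and trains support vector machine and
    random forest classifiers with accuracy, sensitivity and specificity
    evaluation under hold-out splits and stratified cross-validation. A
    seeded synthetic-cohort generator produces band-limited EEG surrogates
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    randomForest,
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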