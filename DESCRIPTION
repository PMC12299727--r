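Package: gaitwin
Title: Temporal Gait Parameters from a Loosely Carried IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for extracting clinically relevant temporal
    gait parameters (stride, stance, swing and double-support time) from a
    single smartphone-like inertial measurement unit carried loosely in the
    hand, trouser pocket or jacket pocket. Provides a seeded synthetic
    treadmill-walking cohort generator with exact ground truth, the
    marker-based gait-event reference algorithm (calcaneus/metatarsal vertical
    minima within fractions of the inter-peak interval), sliding-window
    segmentation and labeling of IMU signals, a compact convolutional +
    recurrent (CNN-LSTM) window classifier with event-time reconstruction,
    per-cycle parameter derivation with quality filtering, and an agreement
    battery (relative RMSE summaries, Pearson association tiers, Bland-Altman
    bias and limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    e1071
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
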