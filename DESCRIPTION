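Package: nightscratch
Title: Nocturnal Scratch Detection and Digital Endpoints from Wrist-Worn Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end assessment of nocturnal scratching in atopic dermatitis
    from wrist-worn 6-axis inertial sensors: autocalibration to local gravity,
    resampling, accelerometer-only and gyroscope-fused gravity removal,
    threshold-based hand-movement detection, temperature-based non-wear
    detection, total-sleep-opportunity estimation, an interpretable
    time/frequency/topological feature bank (zero-dimensional sublevel-set
    persistence statistics and Gaussian persistence curve norms), learned
    convolutional and bidirectional-recurrent window embeddings ensembled
    under a gradient-boosted classifier with recursive feature elimination and
    leave-one-subject-out evaluation, and per-night digital endpoints (scratch
    duration and intensity) with Bland-Altman, intraclass-correlation and
    patient-reported-outcome agreement statistics. Includes a seeded synthetic
    night simulator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
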