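Package: bingesense
Title: Predicting Imminent Binge-Drinking Events from Passive Smartphone Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting imminent, same-day
    binge-drinking events (BDEs) from passively sensed smartphone data.
    Provides a seeded synthetic cohort generator emulating a 14-week
    young-adult mobile-sensing study, 15-minute epoching and event labeling
    from self-reported drinking logs, a 70-feature registry spanning GPS
    mobility metrics (radius of gyration, location entropy, circadian
    movement via Lomb-Scargle), accelerometer, communication, device-use and
    environment features, an analysis-window by prediction-distance model
    search over weekday and weekend gradient-boosting classifiers with SMOTE
    imbalance handling, chance-corrected evaluation, and an explanation layer
    (per-class Shapley attributions, partial dependence, and binned
    location-probability maps) to support just-in-time adaptive
    intervention design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    stats,
    utils,
    xgboost,
    randomForest,
    rpart,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
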