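Package: postopwear
Title: Early Detection of Abnormal Postoperative Recovery from Consumer
    Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting abnormal postoperative recovery in
    children after appendectomy from consumer wearable (Fitbit-style) data.
    Includes a synthetic cohort generator (patients, postoperative events,
    minute-level heart-rate and step streams, daily activity and sleep
    summaries), per-day feature engineering with temporal change variants,
    ground-truth day labeling around postoperative events, a balanced random
    forest classifier evaluated under leave-one-subject-out cross-validation,
    and event-level early-detection metrics with sensitivity analyses for
    data availability, wear time, device type, and pooled patient groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
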