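Package: pdmotor
Title: Motor-Symptom Estimation for Parkinson's Disease from Multi-Device Wearable IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts synchronized five-device (wrists, ankles, waist)
    nine-axis inertial recordings into 30-minute estimates of Parkinson's
    disease motor symptoms: resting tremor, bradykinesia, dyskinesia, gait
    impairment, freezing of gait and the medication OFF state. Implements
    windowed time/frequency motion features, a wrapper-selected Gaussian
    Naive Bayes activity classifier with leave-one-subject-out evaluation,
    spectral wrist-tremor detection with a fuzzy linear map to UPDRS item 20,
    shank angular-velocity step detection with a linear gait-impairment model,
    freeze-index based freezing-of-gait detection, and a Naive Bayes OFF-state
    estimator with ReliefF feature importance. Ships a labeled synthetic-signal
    simulator and the validation statistics used to assess such devices
    (ROC/Youden thresholds, confusion metrics, Bland-Altman, correlations,
    day-to-day ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    rpart,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
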