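Package: pointback
Title: Vestibular Rotation Task Simulation, Movement Features and
    Genetic-Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the blindfolded vestibular rotation ("point back to
    the door") task used to probe path integration in carriers of the APOE
    e3e4 genotype. Simulates seeded cohorts of tablet IMU sensor streams
    (accelerometer, gyroscope, compass) for the nine-trial rotation
    protocol, cleans the raw signals (180-degree device-flip correction,
    compass unwrapping with an 80-degree gate, 100-point moving-window
    smoothing, peak detection), extracts the seven vestibular movement
    features (end error, total angular displacement, tilt, gyroscopic rate
    of change, average acceleration, average jerk, hesitations), and
    classifies genotype group per trial with random forests, support
    vector machines and multi-layer perceptrons under stratified five-fold
    cross-validation with grid search, reporting F1, accuracy and
    normalised feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
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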