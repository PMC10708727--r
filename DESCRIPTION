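Package: harkit
Title: Human Activity Recognition Toolkit with Vision-Based Sensor Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for wearable-sensor human activity
    recognition (HAR) research. Generates synthetic paired recordings of 2D
    pose keypoints (17-keypoint skeleton at 10 Hz) and inertial measurement
    unit streams (14 channels per body location at 60 Hz), consolidates and
    centralizes keypoint series, ranks candidate sensor placements with a
    cross-validated cosine-distance dissimilarity metric over activity
    vectors, fuses pose and IMU streams into labeled fixed-length windows,
    evaluates classifiers under k-fold, leave-recordings-out and
    leave-one-subject-out cross-validation, and trains small CNN-LSTM,
    ResNet-style and DeepConvLSTM window classifiers with last-layer
    transfer learning for on-device-style personalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
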