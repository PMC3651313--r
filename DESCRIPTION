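Package: imusegid
Title: Automatic Identification of Inertial Sensor Placement on Body Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the body segment to which each body-worn inertial
    measurement unit (IMU) is attached from a few seconds of walking data.
    Raw 3D accelerometer and gyroscope signals are levelled using the static
    standing posture, tracked with strapdown gyroscope integration, and
    aligned to a gait frame whose x-axis points along the walking direction.
    Per-sensor signal features (RMS, variance, inter-axis and inter-sensor
    correlations of accelerations, angular velocities and angular
    accelerations) are fractionally ranked within each trial and classified
    with an entropy-based (C4.5-style) decision tree; left and right limbs
    are disambiguated by correlating limb accelerations with trunk roll and
    with already-resolved adjacent segments. A synthetic gait simulator
    generates labelled walking trials for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
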