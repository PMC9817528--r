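Package: EquiGait
Title: Five-Gait Classification of Icelandic Horses from Smartphone Inertial Sensors
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying the five gaits of the Icelandic horse
    (walk, trot, toelt, canter, flying pace) from smartphone inertial
    sensor logs. Implements reading and resampling of phone IMU, GPS and
    gait-label event logs; quaternion rotation of device-frame signals to
    the world frame and GPS-heading rotation to the horse frame; sliding
    window segmentation with transition exclusion; recurrent (LSTM,
    bidirectional LSTM, GRU) and dilated 1-D convolutional sequence
    classifiers with a self-contained training engine; exponential-decay
    and majority-vote smoothing of prediction streams; micro, one-vs-all
    and macro accuracy metrics with leave-one-horse-out cross-validation;
    a judge-panel agreement protocol with transition exclusion periods;
    and a synthetic ride simulator that generates gait-periodic IMU
    traces, GPS tracks, label events and judge streams for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, geosphere, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
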