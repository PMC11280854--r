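Package: signstream
Title: Sign Language Recognition from Dual-Armband sEMG and IMU Streams
Version: 0.1.0
Authors@R: person("signstream", "developers", email = "signstream@example.org",
    role = c("aut", "cre"))
Description: A hardware-independent pipeline for real-time sign language
    recognition from two forearm-worn armbands, each providing eight surface
    electromyography (sEMG) channels at 200 Hz and a 10-value inertial
    measurement unit (IMU) frame at 50 Hz. Provides a seeded synthetic stream
    generator emulating a two-armband recording session, threshold-based
    motion segmentation of continuous streams, a 1044-dimensional
    time/frequency/entropy feature bank per detected sign, multiclass
    classifiers with cross-validation and train/test-split evaluation
    (accuracy, Cohen's kappa, probability RMSE), plain-text dataset storage,
    ARFF export for Weka interoperability, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
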