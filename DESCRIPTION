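Package: tapdecode
Title: Decoding Finger-Tapping Kinematics from Delta-Band Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing continuous single-joint finger
    kinematics from multichannel scalp EEG. Implements a lag-embedded
    linear (Wiener-style) decoder on delta-band EEG derivatives, genetic
    algorithm channel selection inside a nested cross-validation,
    movement onset/offset detection and trial statistics, Thomson
    multitaper spectral estimation with alpha/beta event-related
    (de)synchronization maps, and a synthetic EEG-plus-kinematics
    session generator with planted, recoverable ground truth for
    validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
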