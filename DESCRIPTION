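Package: gaitkine
Title: Gait Analysis from Body-Mounted INS/GPS Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes fused INS/GPS output streams (400 Hz velocity,
    acceleration, orientation and angular rate in the North-East-Down frame)
    into anatomical-frame gait kinematics. Steps are segmented at the
    negative-going zero crossings of high-pass filtered vertical velocity
    (the centre-of-mass apex), and a per-step metric set is computed
    (cadence, step length, speed, vertical oscillation, lean, body rotation,
    contact time, duty factor, flight metrics, mechanical energy). Includes
    a boundary-shift robustness experiment, recurrent sequence models (GRU
    or LSTM, trained natively with masked losses) for indirect estimation of
    ground contact and vertical ground reaction force from the six inertial
    channels, instrumented-insole stream handling, and a synthetic gait
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
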