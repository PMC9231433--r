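Package: handsfree
Title: Hands-Free Sensing Interfaces for Power Wheelchair Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for hands-free human-machine interfaces that steer a
    power wheelchair: head-tilt control from 3-axis accelerometer readings
    with a cubic dead-zone voltage map, eye-gesture recognition from
    two-channel infrared oculography (exponential-moving-average smoothing,
    DC-blocker filtering, and a small feed-forward neural network), and an
    attention/orientation voice-command grammar. Includes seed-reproducible
    synthetic signal generators for all three channels, a planar unicycle
    wheelchair simulator with an ultrasonic anti-collision gate, and
    Wheelchair Skills Test capacity scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
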