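Package: imgval
Title: On-Field Validation of Instrumented-Mouthguard Head Acceleration Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for on-field validation studies of
    instrumented mouthguards (IMGs) in collision sport. Generates synthetic
    multi-sensor IMG recordings (three ~3,200 Hz triaxial accelerometers and an
    800 Hz gyroscope) together with ground-truth impact logs and imperfect
    video-coded contact-event logs; implements the device signal chain
    (trigger-threshold event capture with window extension, resampling,
    zero-phase Butterworth low-pass filtering, rigid-body transformation of
    sensor accelerations to the head centre of gravity, peak linear and
    rotational acceleration extraction); matches head acceleration events to
    video-coded contact events; and computes diagnostic accuracy (sensitivity,
    positive predictive value under visually-verified, best-case and worst-case
    handling of unclear events), athlete-exposure rates, stratified impact
    magnitude summaries, non-parametric group comparisons and inter-rater
    agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
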