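Package: imugait
Title: Virtual Inertial Sensor Synthesis and Threshold-Based Gait Event
    Detection from Rigid-Body Limb Kinematics
Version: 0.1.0
Authors@R:
    person("Lennart", "Brandt", email = "lennart.brandt@posteo.net",
           role = c("aut", "cre"))
Description: Synthesises triaxial accelerometer and gyroscope signals from
    time series of rigid-body segment poses (rotation matrix plus origin) at
    arbitrary virtual sensor positions on cylindrical limb surrogates and a
    shoe surrogate, runs threshold-based gait event detectors (initial
    contact, mid stance, toe off, mid swing) for 1-, 2- and 4-phase gait
    models, and evaluates event timing error (MAE, nMAE) under several
    cross-validation strategies, including rotatory versus translatory
    sensor-repositioning analyses.  A deterministic synthetic gait generator
    with exact ground-truth events and a synthetic vertical ground reaction
    force makes the whole pipeline testable without external motion data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
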