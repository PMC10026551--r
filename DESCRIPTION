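Package: mhtcontrol
Title: Temperature-Feedback PID Control Toolkit for Magnetic Hyperthermia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for designing and verifying temperature-feedback
    controllers for magnetic hyperthermia therapy devices. Translates transient
    performance requirements (rise time, overshoot, settling time) into s-plane
    pole constraints, identifies a two-time-constant plant model from step and
    pulse responses, synthesizes PID gains by pole placement against a target
    second-order closed loop, and executes the discrete loop with actuator
    saturation, RC rate limiting, a safety temperature interlock, and CEM43
    thermal-dose accounting. Includes an axisymmetric finite-volume simulator of
    an agarose-gel and copper-wire induction-heated phantom, a sensor
    signal-chain emulator (Butterworth low-pass filtering, block averaging,
    signal-to-noise reporting), and Morris elementary-effects screening, Sobol
    variance decomposition, and Monte-Carlo uncertainty propagation for the
    thermal model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
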