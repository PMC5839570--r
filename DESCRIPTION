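Package: phstat
Title: Open-Source pH-Stat Control, Seven-Segment Display OCR and Titration Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Software toolkit for webcam-based pH-stat instruments: optical
    decoding of seven-segment pH-meter displays with geometry and threshold
    calibration, volume-to-actuation models for peristaltic and syringe pump
    modules with calibration fitting and a line-oriented command protocol,
    an adaptive dosing controller that holds a reaction at a pH setpoint,
    stability-gated potentiometric titration with equivalence-point
    estimation, and a simulated chemical plant (strong acid/base equilibria,
    acid-generating kinetics, electrode lag, noisy virtual pumps, rendered
    display frames) so the entire closed loop can be exercised and verified
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
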