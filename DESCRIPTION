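Package: hrpwm
Title: Harmonic-Reduction PWM Excitation Design and Thermal Lesion
    Modelling for Focused Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing switched multilevel drive waveforms for
    high-intensity focused ultrasound (HIFU) transmitters.  Implements
    harmonic-reduction pulsewidth modulation (HRPWM) by
    quarter-wave-symmetric switching-angle optimisation, bi-level and
    sinusoidal reference excitations, harmonic spectroscopy of periodic
    drives, compilation of five-level bridge gate schedules with
    dead-time and on-time checking, true electrical power from
    voltage/current records, a linear per-harmonic focused-bowl acoustic
    field model, Pennes bioheat and CEM43 thermal-dose lesion
    prediction, and passive cavitation detection analysis, together with
    seeded synthetic fixtures, text-based persistence and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
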