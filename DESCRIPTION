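Package: pulsesim
Title: Simulation of Arterial Pulse Waves in Healthy Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A one-dimensional computational model of arterial pulse wave
    propagation for building virtual-subject databases across the adult age
    range. Arterial segments are thin viscoelastic tapering tubes terminated
    by three-element windkessel models of the vascular beds; a parameterised
    aortic inflow waveform drives the system. Cardiovascular properties
    (heart rate, stroke volume, ejection time, arterial diameter, pulse wave
    velocity, mean pressure) are prescribed per age decade from
    literature-derived tables and varied on a +/-1 SD grid to generate
    virtual populations. Pressure, flow-velocity, luminal-area, flow-rate and
    photoplethysmogram pulse waves are simulated at common measurement sites,
    and clinically used pulse wave indexes (blood pressure statistics,
    augmentation index, pulse transit times and velocities, PPG stiffness
    indexes) are extracted. Includes scripted case-study analyses of pulse
    pressure amplification, PPG surrogates of aortic stiffness, and pulse
    contour cardiac output algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    jsonlite,
    signal,
    stats,
    utils,
    ggplot2,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
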