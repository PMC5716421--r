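Package: vmatqa
Title: Delivery Simulation and Analysis for VMAT Linac Commissioning Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates the dynamic test deliveries used to commission
    volumetric-modulated arc therapy (VMAT) on Elekta-style linear
    accelerators (picket fences with and without intentional errors,
    maximum-speed consistency fields, dose-rate/gantry-speed and MLC-speed
    strip patterns, rapid leaf reversals, dose-rate change junctions),
    simulates their delivery on a kinematic machine model with binned dose
    rates, axis speed limits and injectable delivery errors, renders
    fluence onto EPID or diode-array detector models, and analyses the
    resulting images and chamber readings into machine-readable QA
    reports (picket peak positions, strip uniformity, junction transition
    widths, reversal overdose rates, monitor-chamber stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
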