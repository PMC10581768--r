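Package: cvrsim
Title: Coupled Cardiovascular-Respiratory Lumped-Parameter Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop six-compartment lumped-parameter model of
    the human cardiovascular system with ventricular interaction through the
    septum and pericardium, optional inertial ('open on pressure, close on
    flow') valve dynamics, coupling to a Lienard-oscillator central respiratory
    pattern generator with passive lung and chest-wall mechanics, an integral
    feedback correction that stabilizes the respiratory muscle pressure over
    long horizons, and a phase-warped time-varying elastance cardiac driver
    that accepts an arbitrary heart-rate profile. Provides verbatim literature
    parameter presets, adaptive Runge-Kutta integration with dense output,
    per-beat and per-breath haemodynamic metrics, tidy accessors and ggplot2
    visualisations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    withr
Config/testthat/edition: 3
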