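Package: vpfilm
Title: Viscoplastic Liquid Films with Surfactant in Liquid-Lined Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the surface-tension-driven (Rayleigh-Plateau) instability
    of a Bingham yield-stress liquid film coating the interior of a rigid
    cylindrical tube, with an insoluble surfactant monolayer at the gas-liquid
    interface. Implements two reduced models from viscoplastic lubrication
    theory: a thin-film system for layers much thinner than the tube radius,
    and a long-wave system for layers of arbitrary thickness that retains the
    exact interface curvature. Provides yield-surface computation and flow-regime
    classification, stiff method-of-lines time integration with plug-formation
    detection, marginally-yielded static profiles by continuation, late-time
    asymptotic diagnostics, shock-speed (Rankine-Hugoniot) diagnostics,
    parameter sweeps, critical-thickness bisection, and conversion of
    dimensionless plugging times to physiological time scales for airway
    mucus plug formation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
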