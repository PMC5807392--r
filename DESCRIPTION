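Package: mcellhab
Title: Mauthner-Cell Escape Circuit Model and Startle Habituation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a two-cell Mauthner (M-cell) startle
    escape circuit modeled as coupled modified Morris-Lecar neurons with a
    calcium-dependent potassium current and a slow, calcium-regulated
    activity-dependent adaptation variable. Provides periodic pulse-train
    stimulation protocols, quasi-steady-state initialization, fixed-step
    Runge-Kutta integration of the circuit, per-stimulus response detection,
    the Faithfulness response-rate statistic, suprathreshold-area return maps
    with five-type pattern classification, a firing-boundary ("jump-up")
    scan in the slow calcium/adaptation plane, Faithfulness parameter scans,
    and behavioral response-raster summaries with a seeded synthetic raster
    generator emulating status-dependent habituation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
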