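Package: velopace
Title: Pacing Strategy Optimization for Road Cycling Time Trials
Version: 0.1.0
Authors@R: person("velopace", "developers", role = c("aut", "cre"),
    email = "velopace@example.org")
Description: Physics-based simulation and optimization of pacing strategies
    for road cycling individual time trials. Models the force balance on a
    rider (aerodynamic drag with vector wind, rolling resistance, grade,
    acceleration), racing-line cornering geometry with friction-limited safe
    speeds, and a finite above-recovery energy budget. A real-coded genetic
    algorithm allocates per-segment speeds to minimize total course time
    subject to the energy budget, with a brute-force grid oracle for
    validation. Includes course ingestion from delimited tables and GPX
    profiles, elevation-profile segmentation, and reproducible report
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
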