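Package: myostep
Title: Simulation and Analysis of Processive Motor Stepping Under Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-molecule analysis of processive cytoskeletal
    motors such as myosin-5. Provides a Gillespie simulator of load-dependent
    stepping kinetics, synthesis and analysis of ultrafast force-clamp
    optical-tweezers position records (event detection, bidirectional step
    detection, run assembly, per-force statistics), quantum-dot localization
    and tracking for TIRF motility assays, Bell-type exponential
    force-dependence and Michaelis-Menten fitting, stall-force estimation,
    and correction of run lengths censored by a finite dumbbell oscillation
    window.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
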