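Package: myovasim
Title: Mechanistic Simulation and Analysis of Myosin Va Ensemble Cargo
    Transport on Suspended 3D Actin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven stochastic simulation of lipid-bound cargo
    transport by ensembles of membrane-anchored myosin Va motors along
    suspended actin filaments, through 3D actin filament intersections
    (tug-of-war directional outcomes) and against an optical trap (stall
    force saw-tooth traces).  Includes the companion measurement toolkit:
    interaction-geometry predicates, sinusoidal helix fitting with
    handedness calls, approach-angle and filament-separation estimation,
    directional outcome classification and straight-to-turn regime maps,
    Kaplan-Meier run-length estimation, sliding-window stall-peak
    detection with Gaussian-mixture decomposition, and photobleaching
    variance-based motor counting, together with seeded synthetic-data
    generators for every analysis input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mclust,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
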