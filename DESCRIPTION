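Package: cerebrofsi
Title: Fluid-Structure Interaction Modelling of Stenosed and Aneurysmal
    Cerebral Artery Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, fully parametric pipeline for studying how
    atherosclerotic stenosis alters hemodynamics in an intracranial artery
    bifurcation and in an atherosclerotic saccular aneurysm. Provides
    Herschel-Bulkley blood rheology with analytic plane-channel oracles, an
    incompressible neo-Hookean arterial wall model with thin-wall membrane
    equilibria, a deterministic block-structured generator for the three
    study geometries (intact bifurcation, stenosed artery, aneurysm), a
    stabilized equal-order finite-element solver for steady
    generalized-Newtonian flow, quasi-static partitioned fluid-structure
    coupling with Aitken relaxation, and wall-shear-stress extraction with
    cross-scenario comparative reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
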