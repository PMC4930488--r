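Package: podburst
Title: Multi-Scale Morphomechanics of Explosive Seed Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the morphomechanics of
    explosive pod shatter in Cardamine hirsuta and related crucifers.
    Implements the trilayer elastic energy landscape of the fruit valve
    (hinged versus boxed lignified endocarp-b geometry), planar discrete
    elastic rod dynamics of valve coiling with breakable viscoelastic seed
    tethers, ballistic seed flight with aerodynamic drag and Monte Carlo
    dispersal fields, an orthotropic membrane finite-element model of
    pressurized exocarp cells (osmotic steps, microindentation stiffness,
    wall-parameter calibration, cell-file tension), organ-level elastica
    fitting of extensometer force-displacement curves, quantification
    operators for cell deformation and fibril orientation, and seeded
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
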