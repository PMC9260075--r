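Package: cochleaVC
Title: Volume-Conductor Modelling of Cochlear-Implant Electrode Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parametric three-dimensional volume-conductor model of the
    human cochlea with an inserted cochlear-implant electrode array.
    Generates a tapering, spiralling scala tympani bounded by a
    low-conductivity cochlea wall and a high-resistivity basilar-membrane
    layer, embedded in bone, with a 16-contact silicone-carrier array
    inside; meshes it with labelled tetrahedra; solves the quasi-static
    Laplace problem for injected contact currents by the finite element
    method; and maps electrode-to-ground impedance as a function of
    electrode proximity to the cochlea wall, insertion depth, and tissue
    conductivity. Includes analytic verification oracles (disk spreading
    resistance, concentric spheres, one-dimensional bars with thin
    resistive layers) and mesh-convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    rlang,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
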