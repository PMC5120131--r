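Package: cochleavc
Title: Patient-Specific Volume-Conduction Modelling of the Electrically
    Stimulated Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parametric cochlear geometries from six landmark points
    measured on clinical cone-beam CT scans, registers cochlear-implant
    electrode arrays into the model frame by orthogonal Procrustes analysis,
    solves the quasi-static volume-conduction problem for monopolar
    stimulation on a labelled tissue voxel grid, emulates intra-cochlear
    back-telemetry voltage matrices, validates model predictions against
    measured matrices with a bias-removed RMS error, optimizes the
    scala-tympani to bone conductivity ratio, and couples the field to a
    stochastic auditory-nerve fiber population via the activation function.
    Includes a seeded synthetic-cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
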