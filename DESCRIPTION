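Package: TFMtools
Title: Traction Force Microscopy from Bead Images to Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end traction force microscopy (TFM) analysis for cells on
    elastic substrates: fluorescent bead detection (difference-of-Gaussian
    filtering and minimum-eigenvalue corner response), pyramidal optical-flow
    displacement tracking, regularized Fourier transform traction cytometry
    (FTTC) on the Boussinesq elastic half-space, per-cell contractility
    readouts (strain energy, maximum and mean traction within the cell
    region), and nonparametric two-group statistics. Includes a synthetic
    forward-model scene generator with known ground truth for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TFMtools-package.R'
    'bead-tracking.R'
    'cell-metrics.R'
    'group-stats.R'
    'io.R'
    'methods.R'
    'substrate-mechanics.R'
    'synthetic-scene.R'
    'pipeline.R'
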