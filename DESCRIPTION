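Package: beeRF
Title: Receptive-Field and Polarization Analysis of Insect Photoreceptor Recordings
Version: 0.1.0
Authors@R: person("beeRF", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for intracellular recordings from single
    photoreceptors of the insect compound eye, built around the dorsal rim
    area (DRA) of bee eyes. Reconstructs spatial receptive fields from
    grid-scan flash protocols, transforms voltage responses to relative
    sensitivities through fitted Hill intensity-response functions, fits
    weighted multi-component elliptical Gaussian receptive-field models,
    detects photoreceptor coupling between neighbouring ommatidia, computes
    polarization sensitivity and preferred e-vector angles, classifies cells
    by eye region and runs the associated group statistics. Includes a
    synthetic-recording simulator with known ground truth so that every
    stage of the pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
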