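Package: spinemargin
Title: Geometric Target Margins for Pediatric Proton Craniospinal Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geometric spinal target design in proton craniospinal
    irradiation of skeletally immature patients. Measures per-vertebra
    water-equivalent depths on planning CT by posterior ray tracing, fits the
    piecewise-linear ventral/dorsal margin model with an age-dependent growth
    factor derived from body surface area, expands the spinal canal into a
    simulated technical clinical target volume (stCTV) and a beam-specific
    planning target volume (bsPTV), and scores agreement against a reference
    contour with slice-averaged Hausdorff distance, mean distance-to-agreement,
    Dice and Jaccard coefficients. Includes a synthetic pediatric spine phantom
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
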