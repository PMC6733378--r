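Package: hipSSM
Title: Statistical Shape Modelling of Proximal Femur Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based statistical shape modelling of the proximal
    femur as applied to hip DXA images: generalized Procrustes alignment,
    principal-component hip shape modes (HSMs), projection of new shapes
    onto a frozen reference model, point-placement reproducibility metrics
    (point-to-point distances and intraclass correlation), and
    spectral-decomposition estimates of the effective number of
    independent modes. Includes a synthetic femur-landmark population
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
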