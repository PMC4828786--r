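Package: balloonmech
Title: Inflation Mechanics of Non-Compliant Valvuloplasty Balloons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Axisymmetric hyperelastic membrane finite-element solver for
    non-compliant valvuloplasty balloon inflation under volume-controlled
    loading, free or inside a compliant cylindrical implantation-site
    phantom. Includes Ogden material evaluation and fitting from uniaxial
    tensile data, Laplace-law compliance analysis of thin-walled vessel
    phantoms, fluoroscopy-style geometric calibration and solid-of-revolution
    volumetry, curve-comparison validation metrics (RMSE of pressure and
    diameter at equal volume), and seeded synthetic-data generators for every
    experimental input so all pipelines are testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
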