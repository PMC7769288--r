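Package: ahglm
Title: Adaptive Region-of-Interest ANCOVA for Grey-Matter Volumetrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Atlas-based regional grey-matter volume analysis for
    voxel-based morphometry studies. Extracts per-region tissue volumes
    from modulated NIfTI tissue maps, fits an adaptive per-region ANCOVA
    whose covariates (age, total intracranial volume) and group-by-covariate
    interactions are included only when they pass explicit screening rules,
    controls the false discovery rate with Storey-Tibshirani q-values, and
    reports partial eta-squared effect sizes. Ships a synthetic-cohort
    generator that reproduces the statistical structure of a two-group
    morphometry study so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
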