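Package: corticalfd
Title: Box-Counting Fractal Dimension of Cortical Ribbon Masks and
    Cohort-Level Complexity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the three-dimensional box-counting fractal dimension
    (FD) of binary voxel masks such as FreeSurfer cortical ribbons, builds
    hemisphere and lobar masks from Desikan-Killiany parcellation label
    volumes, and fits the cohort-level statistical battery used in ageing
    studies of cortical complexity: linear and quadratic age models with AIC
    comparison, sex-stratified and age-by-sex interaction models, normalized
    left-right asymmetry indices with their own model set, five-year age
    subgroup trajectories, and per-measure extreme-outlier screening.
    Includes generators for analytic fractal phantoms (Menger sponge,
    fractal percolation) and simulated cohorts so the whole pipeline is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
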