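Package: devrsa
Title: Developmental Representational Geometry of Category-Selective Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how category-selective cortical
    representations reorganize across development. Implements
    leave-one-run-out cross-validated representational similarity matrices,
    exhaustive binary partition-model ranking, Procrustes geometry metrics
    (alignment, template similarity, dispersion, convex-hull spread),
    leave-one-subject-out cross-subject decoding with label-permutation
    nulls, a stability-versus-coupling coordinate framework, laterality and
    topography summaries, and quantitative-MRI tissue-trajectory analyses.
    Ships a seeded synthetic-cohort generator emulating the statistical
    structure of a two-group (children, adults) category-localizer fMRI
    study, so every stage of the pipeline is testable without data
    downloads. All user-facing functions take data frames and return
    tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
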