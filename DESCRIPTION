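Package: saxdev
Title: Development of Functional Connectivity Along the Sensorimotor-Association Axis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how cortico-cortical functional connectivity
    changes with age along the sensorimotor-association (S-A) axis of cortical
    organization. The package computes regional connectivity metrics (FC
    strength, between- and within-network connectivity, edge-level
    connectivity) from parcellated BOLD timeseries, models age effects with
    penalized-spline generalized additive models and signed adjusted-R-squared
    effect sizes, tests spatial alignment of effect maps with axis ranks using
    spin-based spatial permutation nulls, traces age-resolved alignment
    trajectories with posterior credible bands, and summarizes edge-level age
    effects as smooth surfaces over pairs of axis ranks. A synthetic-cohort
    generator with planted hierarchical age effects supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
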