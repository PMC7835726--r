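Package: uprightr
Title: Multisensory Observer Models of Verticality Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Gaussian observer models of head-in-space and body-in-space
    verticality perception to rod-and-frame and subjective-postural-vertical
    trial data. Percepts are modelled as convex combinations of a direct sensory
    estimate and an indirect estimate corrected for neck tilt, under three
    weighting regimes (direct-only, freely weighted, and reliability-weighted
    maximum-likelihood combination), compared per participant by BIC. Includes a
    seeded synthetic-cohort generator reproducing the crossed visual x platform
    x head-tilt design, trial exclusion and head-upright mean correction,
    rigid-body center-of-pressure posture checks, and an end-to-end pipeline
    runner with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
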