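Package: approachscan
Title: Classifying Distance- and Spatial-Frequency-Tuned Visual Neurons
    from Slow-Approach Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings made while an
    observer slowly approaches a large stationary grating. Converts spike
    trains to spike-density curves along the approach trajectory, tests
    response maxima with a trial-resampling bootstrap, computes the
    maximum-shift statistic between gratings of doubled spatial frequency,
    and classifies neurons as spatial-frequency tuned (shifting maximum)
    or absolute-distance tuned (constant maximum). Includes a
    viewing-geometry model of retinal spatial frequency and drift, an
    inhomogeneous-Poisson simulator of archetypal neurons for end-to-end
    validation, population-level normality and cluster analyses, and a
    demonstrative ratio-code decoder of absolute distance from overlapping
    tuning curves.
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
    mclust,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
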