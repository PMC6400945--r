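Package: symspeed
Title: Speed-Tuned Mirror-Symmetry Detection: Stimuli, Simulated Observers
    and Probability Summation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop, fully synthetic pipeline for studying speed tuning
    in mirror-symmetry detection. Generates limited-lifetime dynamic dot
    patterns with controllable position and motion-direction symmetry,
    simulates two-interval forced-choice observers built from speed-selective
    symmetry channels, runs one-up three-down adaptive staircases, fits
    logistic psychometric functions with bootstrap threshold errors, and
    implements the signal-detection-theory probability-summation model that
    predicts non-segregated from segregated performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
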