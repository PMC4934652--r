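Package: tiltchron
Title: Chronometric Decomposition and Congruency Statistics for
    Tilt-Response Audiovisual Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for speeded two-alternative forced-choice experiments in
    which responses are registered by tilting a handheld tablet. Builds
    balanced audiovisual rate-discrimination sessions (6 vs 8 Hz visual size
    modulation crossed with congruent or incongruent auditory amplitude
    modulation), synthesizes the stimuli, simulates players with controllable
    congruency effects, decomposes 60 Hz accelerometer tilt traces into
    reaction time and movement time via a threshold-crossing and
    movement-onset criterion, flags unusable subjects, and computes
    cohort-level congruency-effect statistics (paired t tests,
    within-subject standard errors, speed-accuracy correlation, and age
    regressions) with tidy outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
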