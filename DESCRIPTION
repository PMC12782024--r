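Package: tempobisect
Title: Temporal Bisection Psychophysics and Regional Grey-Matter Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditory temporal bisection experiments in clinical
    cohorts: constrained trial-schedule generation for a 2x2 (semantic
    category x valence) design with seven stimulus durations, a
    scalar-timing (pacemaker-accumulator) responder simulator for building
    synthetic cohorts, maximum-likelihood psychometric curve fitting with
    guess and lapse asymptotes, extraction of bisection point and Weber's
    ratio, linear mixed-model group contrasts, and signed-difference
    regional grey-matter association testing with family-wise error
    control by max-statistic permutation within regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
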