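Package: oddpupil
Title: Simulation and Mixed-Model Analysis of Auditory Oddball Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for event-related pupillometry in auditory oddball
    paradigms with reward manipulations. Provides a synthetic-session
    simulator with known ground truth (tone sequences, phasic pupil
    responses, tonic block effects, slow drift, blinks, gaze wander,
    manual responses), readers and writers for tab-separated sample,
    event and calibration files, sample-level preprocessing (blink and
    gaze-deviation masking, margin extension, linear interpolation,
    mean-preserving detrending, affine calibration to mm^2), per-trial
    epoch scoring (baseline and response means, change scores, error
    exclusions), and linear mixed-effects analysis with sum contrast
    coding, estimated marginal means, Holm-Bonferroni contrast families,
    a tonic baseline model and a repeated-measures response-time ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    zoo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
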