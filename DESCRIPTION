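Package: segmot
Title: Sensory-Memory Signatures in Event-Segmented Multiple-Object Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for partial-report studies of
    visual sensory (iconic) memory with moving stimuli. Generates constrained
    bilinear-trajectory multiple-object-tracking displays, builds blocked
    trial schedules for duration, cue-delay and set-size manipulations,
    simulates observers under competing memory architectures (sensory memory
    allocated exclusively to the current event segment versus shared across
    segments, plus overwriting and guessing controls), scores direction
    reports with the transformed-performance statistic TP = 1 - |error|/180,
    and runs the sensory-memory signature battery (delay decay, single-report
    advantage, single-report versus first full report) with repeated-measures
    ANOVA, Mauchly's sphericity test and Greenhouse-Geisser correction to
    classify which architecture generated a data set.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
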