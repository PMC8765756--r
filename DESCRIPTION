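Package: lcacc
Title: Spike-Count Statistics and Pupil-Linked Arousal Analysis for
    Paired Brainstem-Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous locus coeruleus (LC) and
    anterior cingulate cortex (ACC) recordings during fixation: binned
    spike-count statistics (mean, variance, Fano factor) conditioned on
    partner-region firing, pairwise spike-count correlations with
    z-scored outlier removal, shuffle controls and tercile partitions,
    pupil hippus cycle detection with four-landmark phase assignment and
    phase-triggered maps, startle-evoked burst-pause classification with
    fake-event controls, and nonparametric resampling statistics. Ships
    a common-input Poisson session generator whose correlation, Fano,
    phase-delay and evoked-response ground truth is known analytically.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
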