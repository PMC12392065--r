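Package: mifind
Title: Mental Finger Individuation Analysis for TMS Neurofeedback Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for transcranial magnetic stimulation (TMS)
    neurofeedback studies of mental finger individuation. Processes per-trial
    electromyography (EMG) into normalized motor evoked potentials (MEPs) and
    the MEP target-ratio statistic, reproduces the neurofeedback trial scoring
    and session scheduling logic, implements adaptive maximum-likelihood
    threshold hunting (PEST) for resting motor threshold and paired-pulse
    (SICI/ICF) protocols with the associated inhibition and facilitation
    percentages, computes prewhitened cross-validated Mahalanobis (crossnobis)
    inter-finger distances from run-structured voxel patterns, and performs
    cross-task linear decoding with permutation inference, Fisher p-value
    combination and false-discovery-rate control. A synthetic-data generator
    with known ground truth emulates the EMG trial streams, sigmoidal
    recruitment behaviour and voxel-pattern structure of such studies so that
    every stage of the pipeline can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
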