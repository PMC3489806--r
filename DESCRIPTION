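Package: seizr
Title: Interictal Spike Detection and Seizure Quantification for Rodent EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying epileptiform activity in two-channel rodent
    EEG from repeated low-dose intrahippocampal kainate experiments. Implements
    a baseline-Gaussian interictal spike detector with per-subject calibration
    of the detection threshold against annotated data, rule-based electrographic
    seizure segmentation with focal/generalized classification from Racine-stage
    annotations, status epilepticus flagging, a causal responsive-stimulation
    trigger simulator, per-session seizure and spike-rate metrics, and the
    group-by-day statistics (pooled and paired t tests, split-plot
    repeated-measures ANOVA) used to compare stimulated and sham cohorts. A
    synthetic EEG session generator with full ground truth supports validation
    and power analysis.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
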