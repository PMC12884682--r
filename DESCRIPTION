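Package: miniepoch
Title: Peri-Event Epoch Classification for Miniscope Calcium Imaging of Operant Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing deconvolved one-photon calcium imaging recorded during
    self-initiated operant tasks. Aligns behavioral event logs to 20 Hz calcium event
    traces via shared sync pulses, parses trials into correct/incorrect/omitted outcomes,
    computes per-trial event rates in named trial epochs against a paired intertrial
    baseline, classifies each neuron as excited, inhibited or nonresponsive per epoch with
    a two-tailed paired sign-flip permutation test under Bonferroni familywise control,
    composes mixed-selectivity category strings, and compares populations between groups
    (proportions with chi-square tests, normalized peri-event traces with mixed-design
    ANOVA). Includes a synthetic-session generator with ground-truth tuning so every
    stage is verifiable without animal data, and a pixel-change locomotion index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
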