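Package: vtsfear
Title: Miniscope Calcium Imaging and Synaptic Physiology Analysis for
    Auditory-Cued Fear Conditioning
Version: 0.1.0
Authors@R:
    person("Maxime", "Declercq", email = "maxime.declercq@posteo.net",
           role = c("aut", "cre"))
Description: Analysis pipeline for three-day auditory-cued fear conditioning
    experiments combining miniature-microscope calcium imaging of striatal
    neurons with behavioral freezing readouts and ex-vivo optogenetic
    circuit mapping. Provides non-negative sparse AR(1) deconvolution of
    fluorescence traces, freezing-bout segmentation from a movement index,
    event-triggered Z-score responder classification with confound-trial
    exclusion and cross-plane duplicate removal, state-conditional
    amplitude-weighted event frequencies, population overlap summaries, the
    accompanying nonparametric statistical battery with repeated-measures
    ANOVA power analysis, and EPSC metrics (input-output curves,
    paired-pulse ratio, AMPA/NMDA ratio). A synthetic-data generator with
    planted ground truth makes every stage verifiable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
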