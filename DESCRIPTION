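Package: forktimer
Title: Stochastic Timers for Bacterial Cell-Cycle Progression and Multifork Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling bacterial cell-cycle progression with
    growth-rate-conditioned stochastic timers. Each replication cycle is
    anchored at an initiation event and described by three timers: the
    inter-initiation time, the C period (initiation to termination), and the
    initiation-to-division time. The package estimates per-condition
    calibration curves (conditional timer distributions as functions of
    single-cell growth rate) from single-cell lineage tables, chains
    replication cycles forward without fitting parameters, classifies each
    cycle's replication-fork configuration (2/4/6/8+ forks) from timer
    orderings via a discrete-event chromosome state machine, and provides
    fork-stratified analyses, including a permutation test for fork-number
    dependence of timer trends. A synthetic-data generator with presets for
    slow, intermediate, and fast growth supports end-to-end testing without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
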