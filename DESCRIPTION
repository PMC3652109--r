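Package: rffr
Title: Adaptive Ensemble Docking Campaigns for Reduced Flexible-Receptor Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reduced fully flexible receptor (RFFR) models from
    ensemble-docking campaigns. A fully flexible receptor model is an ensemble
    of receptor conformations (snapshots) from a molecular dynamics trajectory;
    docking every snapshot against a ligand is expensive, so this package
    adaptively prioritises and discards subgroups of clustered snapshots from
    partial free-energy-of-binding results (the P-SaMI data pattern), schedules
    docking tasks into priority-balanced queues dispatched by a simulated
    master-slave worker pool, and evaluates the quality of the reduced model
    against the full ranking. Includes a seeded synthetic docking backend, an
    AutoDock DLG best-energy parser, XML control/update files, and a JSON-lines
    provenance log.
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
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
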