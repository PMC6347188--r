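Package: dockscreen
Title: Steric-Grid Filtering of Receptor Model Ensembles and
    Docking-Based Off-Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for structure-based drug discovery
    against class B G-protein-coupled receptors. Builds ligand-density
    occupancy grids over a binding pocket and scores receptor models by
    steric intrusion into the ligand-occupied region; performs
    model-ensemble filtering and cluster-representative selection;
    evaluates virtual-screening score lists with enrichment factors, ROC
    curves, AUC and BEDROC; correlates small-molecule docking scores with
    clinical drug-risk rankings for off-target analysis; and wraps an
    external AutoDock-VINA-compatible docking engine behind a thin,
    testable adapter. Includes seeded synthetic-data generators so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
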