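Package: docknet
Title: Docking-Based Prediction of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("docknet", "developers", role = c("aut", "cre"),
    email = "docknet@example.org")
Description: Toolkit for inferring protein-protein interactions (PPIs) from
    rigid-body docking runs.  Standardizes the top docking score of a protein
    pair against the score distribution of its high-ranked decoys (the docking
    z-score), calibrates the interaction decision threshold under class
    imbalance (confusion metrics, ROC/AUC, F-optimal threshold sweeps),
    performs structural model quality control (identity/coverage filters,
    Kabsch superposition RMSD, TM-score), builds z-weighted interaction
    networks with degree summaries, maps nonsynonymous variants onto
    docked-complex interfaces and classifies binding free-energy perturbations
    (ddG), and runs orthogonal sanity checks (interolog transfer,
    co-localization enrichment, coexpression shift).  A synthetic-data module
    generates parametric decoy score sets, toy structures and toy genomes so
    the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
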