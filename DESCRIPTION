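Package: pdlscreen
Title: Virtual Screening and Assay Analysis for Small-Molecule PD1-PDL1
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated ligand- and structure-based screening workflow
    for small-molecule inhibitors of the PD1-PDL1 immune-checkpoint
    interaction. Provides labeled-corpus assembly with DUD-E style
    property-matched decoy selection, six 2D molecular fingerprint
    featurizers behind a pluggable cheminformatics backend, a Random
    Forest ensemble classifier with at-least-k-of-six consensus
    screening, an AutoDock Vina adapter with a deterministic mock backend,
    per-residue structural interaction fingerprints (SIFt) with a
    key-residue filter language for docking-pose triage, molecular
    dynamics trajectory post-analysis (ligand and backbone RMSD, contact
    persistence), and HTRF plate normalization with four-parameter
    logistic IC50 fitting. A deterministic synthetic-fixture generator
    builds separable SMILES corpora, planted-hit libraries, toy
    protein-ligand complexes and trajectories so the full funnel runs
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
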