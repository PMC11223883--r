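Package: degronkit
Title: Degron Discovery, Proteolysis Simulation and Terminal-Peptide Stability Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline toolkit for protein degradation-signal (degron) analysis.
    Scans protein sequences for degron motifs from a curated, user-extensible
    motif table with N-terminal, C-terminal and internal location classes;
    contextualizes each hit under the tripartite degron model (primary motif,
    candidate ubiquitination sites K/C/S/T as secondary degrons, nearest
    intrinsically disordered region as tertiary degron); computes per-residue
    structural context (relative solvent accessibility normalized by
    residue-type maxima, disorder from pLDDT-bearing structure models or a
    sequence heuristic); simulates proteolytic cleavage with
    PeptideCutter-compatible rules for 35 proteases and re-screens neo-termini
    for N-/C-degrons; scores degron conservation across a multiple sequence
    alignment; and trains and applies gradient-boosted regressors of
    terminal-peptide stability (PSI) with quantile stability categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
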