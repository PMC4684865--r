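Package: costimr
Title: Costimulation Synergy Analysis for Two-Color Microarray Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcriptomic synergy between two
    co-administered immune stimuli measured on two-channel (Cy3/Cy5)
    microarrays. Provides simulation of spot-level two-color arrays with
    known ground truth, background correction and spot filtering, lowess
    intensity-dependent normalization of log2 ratios, per-gene t-test
    calling of upregulated genes at strict and relaxed cutoffs,
    Venn/recruitment accounting of mono- versus costimulation gene sets,
    classification of supra-additively induced genes by the synergy ratio
    FC_combo / (FC_A + FC_B), and coverage-based classification of major
    and minor regulatory network nodes. Ships a reference table of fold
    changes for the 62 genes synergistically upregulated in CAL-1
    plasmacytoid dendritic cells by combined TLR7 ligand stimulation
    (9.2s RNA + CL264).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
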