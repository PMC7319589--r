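Package: abddg
Title: Predicting Binding Affinity Changes of Multi-Point Mutations in
    Antibody-Antigen Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in antibody-antigen binding free energy
    (ddG, kcal/mol) caused by single and multiple point mutations, from a
    complex structure.  Features are graph-based pharmacophore signatures
    (cumulative atom-class pair counts over distance bins around the mutated
    sites), deltas of typed non-covalent interaction networks and solvent
    accessible surface area between wild-type and modelled mutant structures,
    inter-mutation and mutation-to-interface distances, and evolutionary
    scores (PAM30, PSI-BLAST PSSMs).  An ensemble of extremely randomized
    regression trees with greedy forward feature selection is trained on
    curated affinity records, augmented with hypothetical reverse mutations,
    and evaluated with stratified k-fold and leave-one-complex-out cross
    validation.  Includes a design scan enumerating and ranking all double
    and triple mutations at the binding interface, and a synthetic-data
    generator so the whole pipeline is testable offline.
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
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
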