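Package: sumosite
Title: Sequence-Based Prediction of Protein Sumoylation Sites
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts sumoylation sites on lysine residues from protein
    sequence. Builds labeled datasets of 25-residue lysine-centered windows
    from FASTA files and site annotation tables (with terminal padding,
    redundancy filtering at a sequence-identity threshold, and seeded
    negative subsampling to a fixed class ratio), encodes windows under
    eight feature schemes (one-hot binary, k-spaced amino-acid pair
    composition, PSI-BLAST profile rows, BLOSUM62 nearest-neighbour ratios,
    reduced six- and nine-letter alphabets, Z-scale physicochemical
    descriptors, and a hydrophobicity-augmented one-hot scheme), trains a
    radial-basis-function support vector machine via an internal SMO
    solver, and evaluates predictors with stratified k-fold and
    leave-one-out cross-validation, repeated negative resampling,
    sensitivity/specificity/accuracy/Matthews correlation, and ROC/AUC.
    A seeded synthetic proteome generator with planted consensus-motif
    sites makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
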