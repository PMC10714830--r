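Package: triscreen
Title: Tri-Modal Sequence, Domain and Structure Screening for Divergent
    Enzyme Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-wide discovery screen for divergent enzymes that
    combines three search modes: exact Smith-Waterman sequence search with
    Karlin-Altschul E-values, profile hidden Markov model domain search with
    shuffle-calibrated significance, and secondary-structure-element based
    structural search over predicted C-alpha models scored with the Q-score of
    Kabsch-superposed residue alignments. Candidate triage excludes
    already-annotated CAZyme families and reports structure-only hits.
    Includes CAZyme repertoire profiling, taxonomy-tree auxiliary-activity
    density analytics with clade pruning and percentile ranking, a
    glucose-versus-substrate expression cross-reference, and a synthetic-data
    generator that plants close homologs, remote homologs and fold-only
    analogs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
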