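Package: phagehost
Title: Phage Host Genus Prediction from Whole-Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts admissible bacterial host genera for bacteriophages from
    their genome sequences. Coding sequences are extracted with a deterministic
    six-frame ORF scanner, translated gene products are grouped into protein
    families by Smith-Waterman similarity and Markov clustering, each phage is
    represented as an integer vector of cluster counts, and one binary Gini
    decision tree per host genus turns the vector into a multi-label host
    prediction. Includes a seeded synthetic-corpus generator with planted
    genus-specific marker families, per-genus evaluation (sensitivity,
    specificity, informedness), Graphviz tree export, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
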