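Package: codonlink
Title: DNA-Encoded Probabilistic Record Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic record linkage of administrative person registries
    through a DNA-encoding approach. Identification fields (name, date of
    birth, sex, mother's name) are encoded into DNA sequences with a
    key-rotated codon wheel that places confusable characters on adjacent
    codons, so that common typographical and phonetic errors cost a single
    nucleotide. Encoded databases are linked by local sequence alignment with
    percentage-of-self-hit score normalization, and candidate pairs are
    classified as match or non-match by random-forest or logistic-regression
    models trained on simulator-generated labeled data. Companion modules
    provide greedy centroid deduplication, a synthetic person-record simulator
    with a realistic typo-injection error model, and linkage evaluation with
    error profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    Biostrings,
    jsonlite,
    yaml,
    stringi,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
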