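Package: hostforest
Title: Host Genus Prediction for Viruses of Bacteria and Archaea from
    Protein Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the host genus (and full lineage up to domain) of
    viruses of Bacteria and Archaea from protein content. Viral proteins
    are grouped into clusters of homologs, each cluster is turned into a
    position-specific scoring model, and genomes are summarised as a
    genomes-by-cluster matrix of best-hit bit scores that feeds a
    probabilistic multi-class random forest. The package also implements
    the classical alignment-dependent evidence pipeline (CRISPR spacer,
    homology and shared-tRNA matches pooled per viral population with
    3/2/1 point weights), alignment-free MinHash and k-mer frequency
    distances for corroborating predictions, per-rank precision/recall/F1
    evaluation with bootstrap support, genome dereplication and
    AAI-based train/test independence filtering, and a synthetic
    virus-host universe generator with planted, recoverable signal for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
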