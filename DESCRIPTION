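Package: htbgc
Title: Detection of Horizontally Transferred Biosynthetic Gene Clusters in
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biosynthetic gene clusters (BGCs) that were likely
    acquired by horizontal gene transfer within a metagenomic sample. BGCs
    from genome bins are clustered into gene cluster families (GCFs) by
    domain-content similarity; within each family, genomes whose seven-rank
    taxonomy is anomalously distant from the other members are flagged by an
    exponential rank-distance rule; candidates are confirmed by re-clustering
    against reference-genome BGCs of their own taxon (isolation) and by a
    paired per-gene phylogenetic-distance test. Includes a taxonomy-structured
    synthetic community generator with planted transfers and an evaluation
    harness (precision/recall/F1, ROC AUC, transfer-rate contingency tables,
    donor-recipient matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
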