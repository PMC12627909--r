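Package: seedlingID
Title: Molecular Barcoding Decision Procedures for Seedling Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision procedures for identifying plant seedlings from
    molecular barcoding data, built around a sub-Antarctic island flora
    survey design. Evaluates traditional barcoding markers by pairwise
    TN93 genetic distances, haplotype collapsing, barcode-gap summaries
    and liberal tree-based identification; assigns query samples to
    species by phylogenetic placement (monophyly with reference samples)
    and patristic distance; tests pooled samples for species homogeneity
    by SNP density against candidate plastome references; and summarizes
    seedling incidence by invasiveness class, with wind-trap seed-fate
    accounting. A synthetic-data module simulates species trees,
    multi-locus alignments under GTR+Gamma, sequencing reads and mixed
    read pools so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    rlang,
    withr,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
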