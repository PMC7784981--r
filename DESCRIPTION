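Package: panphen
Title: Pangenome Set Algebra, Functional Enrichment, and Gene-Tree
    Screening for Host-Range Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for relating bacterial gene
    content to host-range phenotypes. Loads gene-cluster membership
    tables into a genomes-by-clusters copy-count matrix and computes
    core, group-exclusive-core, and single-copy-core cluster sets;
    scores annotated functions for differential presence across
    phenotype groups with a Rao score (Pearson chi-square) statistic
    and Benjamini-Hochberg q-values; screens per-gene-cluster trees
    for constraint topologies in which sequence variants separate
    phenotype groups, with polytomy-aware split and monophyly
    compatibility; classifies host strains as resistant, permissive,
    or nonpermissive from serial-passage growth curves and locates
    crash points; and generates synthetic pangenomes, gene trees, and
    passage dynamics with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    phangorn,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
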