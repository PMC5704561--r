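Package: phyloscope
Title: Phylogenomics of Diverse Gene Families: Clustering, Iterative
    Profile Trees, HGT Coherence, Selection and Locus Context
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of large, diverse prokaryotic
    gene families such as the Cas4 nucleases of CRISPR-Cas adaptation
    modules. Provides greedy identity/coverage sequence clustering,
    progressive profile alignment with alignment-column filtering,
    an iterative profile-profile cluster merging procedure with UPGMA
    dendrograms and per-cluster neighbor-joining trees grafted into one
    family tree, quantification of horizontal versus vertical evolution by
    Spearman correlation of gene-tree and 16S rRNA patristic distances
    under sentinel and minimum-distance rules, pairwise dN/dS estimation
    (Nei-Gojobori 1986), genomic-context classification of family members
    (CRISPR-associated, solo, mobile-element), and a synthetic-data
    generator with known ground truth (species tree, transfer rate,
    selection strength, locus architecture) for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
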