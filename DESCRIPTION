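Package: mirdisc
Title: miRNA Gene Discovery and Annotation from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and annotating microRNA genes
    from small RNA deep-sequencing libraries and a genome assembly. Reads are
    adaptor-trimmed, size-filtered and collapsed; exact genomic read stacks are
    excised into candidate precursor windows; windows are folded with a
    stacking-aware Nussinov dynamic program and scored by combining hairpin
    stability with Dicer-consistent read-position statistics; the score cutoff
    is calibrated against dinucleotide-shuffled controls to a target
    signal-to-noise ratio. Called precursors are classified as conserved
    orthologs or novel genes by local-alignment homology with Karlin-Altschul
    E-values, screened against repeats and other non-coding RNA, named by
    miRBase-style nomenclature, grouped into duplicate copies, gene clusters and
    cross-contig cluster groups, and quantified into a miRNA-by-sample count
    matrix with total-count normalization, replicate correlation checks and
    negative-binomial one-tissue-versus-rest differential expression tests. A
    synthetic-data generator plants miRNA genes, duplicates, clusters, repeat
    decoys and tissue-specific expression into a toy genome and simulates
    Dicer-processed multi-tissue libraries with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
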