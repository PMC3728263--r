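# Bundled reference tables: a published-style novel miRNA gene table and a
# zebrafish cluster signature table for conservation comparison.

#' Bundled novel miRNA gene table
#'
#' The package's bundled table of novel (non-conserved) miRNA genes: name,
#' mature 5p/3p sequences (RNA alphabet), precursor, locus count and tissue
#' pattern. Used as a fixture for nomenclature and iso-miR accounting.
#'
#' @return A tibble.
#' @export
novel_mirna_table <- function() {
  readr::read_tsv(system.file("extdata", "novel_mirnas.tsv",
                              package = "mirdisc"),
                  show_col_types = FALSE)
}

#' Bundled reference cluster signatures
#'
#' Zebrafish miRNA gene-cluster family signatures used by
#' [compare_cluster_conservation()].
#'
#' @return A tibble with columns `species`, `cluster`, `members`.
#' @export
reference_clusters <- function() {
  readr::read_tsv(system.file("extdata", "reference_clusters.tsv",
                              package = "mirdisc"),
                  show_col_types = FALSE)
}

#' Count distinct mature miRNAs after iso-miR collapsing
#'
#' Numbered suffixes (`-1`, `-2`, ...) mark iso-miR genes: distinct
#' precursor loci producing an identical mature sequence. Collapsing them
#' counts each (family, letter) entity once; lettered variants remain
#' distinct genes.
#'
#' @param names Character vector of miRBase-style gene names.
#' @return Number of distinct matures.
#' @export
count_distinct_matures <- function(names) {
  length(unique(collapse_isomir_names(names)))
}

#' Strip numbered iso-miR suffixes from miRBase-style names
#'
#' A trailing `-N` is an iso-miR suffix only when it follows a complete
#' family token (digits plus optional variant letters): `ssa-mir-7552a-1`
#' collapses to `ssa-mir-7552a`, while `ssa-mir-8156` is a bare family name
#' and is left alone.
#'
#' @param names Character vector of gene names.
#' @return Names with iso-miR suffixes removed.
#' @export
collapse_isomir_names <- function(names) {
  sub("^([A-Za-z]+-(mir|miR|let)-[0-9]+[a-z]*)(-[0-9]+)?$", "\\1", names)
}
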