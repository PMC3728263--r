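# Read preprocessing: quality filtering, 3'-adaptor trimming, size filtering
# and collapsing to unique reads with per-sample counts.

#' Trim the 3' adaptor from reads
#'
#' Removes, from its earliest occurrence in the read, either a full internal
#' adaptor match or a terminal adaptor prefix of at least 2 nt together with
#' everything 3' of it. A terminal overlap of exactly 1 nt is left in place,
#' so a read that merely ends in the adaptor's first base is not touched.
#'
#' @param reads Character vector of read sequences.
#' @param adaptor Adaptor sequence (>= 2 nt). The default is the small RNA
#'   3' adaptor used by the simulator.
#' @return Character vector of trimmed reads.
#' @examples
#' trim_adaptor("ACGTACGTTGGAATTCTC")  # "ACGTACGT"
#' @export
trim_adaptor <- function(reads, adaptor = "TGGAATTCTCGGGTGCCAAGG") {
  assert_that(nchar(adaptor) >= 2, "adaptor must be at least 2 nt")
  out <- toupper(reads)
  adaptor <- toupper(adaptor)
  # iterate to fixpoint: clipping can expose a further terminal adaptor
  # prefix (insert ending in the adaptor's first bases), and trimming must
  # be idempotent
  repeat {
    trimmed <- trim_adaptor_cpp(out, adaptor)
    changed <- trimmed != out
    out <- trimmed
    if (!any(changed, na.rm = TRUE)) break
  }
  out
}

#' Size-filter reads
#'
#' Keep flag for reads whose length lies within the configured window. The
#' default 18-26 nt window brackets the 20-24 nt mature miRNA range with a
#' small margin.
#'
#' @param reads Character vector of read sequences.
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return Logical keep vector.
#' @export
size_filter <- function(reads, min_len = 18, max_len = 26) {
  assert_that(min_len > 0 && min_len <= max_len, "need 0 < min_len <= max_len")
  n <- nchar(reads)
  n >= min_len & n <= max_len
}

#' Collapse per-sample read lists into unique reads
#'
#' @param sample_reads Named list mapping sample id to a character vector of
#'   trimmed, size-filtered reads.
#' @return A tibble with one row per distinct sequence: `sequence`, one count
#'   column per sample, and `total`.
#' @export
collapse_reads <- function(sample_reads) {
  assert_that(!is.null(names(sample_reads)), "sample_reads must be named")
  long <- purrr::imap(sample_reads, function(reads, sid) {
    if (length(reads) == 0) return(NULL)
    tibble(sequence = reads, sample_id = sid)
  }) |>
    bind_rows() |>
    count(.data$sequence, .data$sample_id, name = "count")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  # keep sample columns in input order even when a sample is empty
  for (sid in names(sample_reads)) {
    if (!sid %in% names(wide)) wide[[sid]] <- 0L
  }
  wide <- wide[, c("sequence", names(sample_reads))]
  wide$total <- rowSums(wide[, names(sample_reads), drop = FALSE])
  arrange(wide, dplyr::desc(.data$total), .data$sequence)
}

#' Preprocess one small RNA FASTQ library
#'
#' Quality filtering (default: drop reads carrying any base below Q20 or an
#' `N`), adaptor trimming by the >= 2 nt terminal-overlap rule, and size
#' filtering.
#'
#' @param fastq Path to a FASTQ file (Phred+33).
#' @param adaptor 3' adaptor sequence.
#' @param min_len,max_len Size-filter bounds (nt).
#' @param min_quality Minimum per-base Phred quality; set to 0 to disable.
#' @return A list with `reads` (kept read sequences, character) and `summary`
#'   (one-row tibble: `total_reads`, `total_trimmed_reads`,
#'   `total_size_filtered_reads`).
#' @export
preprocess_fastq <- function(fastq, adaptor = "TGGAATTCTCGGGTGCCAAGG",
                             min_len = 18, max_len = 26, min_quality = 20) {
  seqs <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                       with.qualities = TRUE)
  n_raw <- length(seqs)
  reads <- as.character(seqs)
  if (min_quality > 0 && n_raw > 0) {
    quals <- Biostrings::PhredQuality(S4Vectors::mcols(seqs)$qualities)
    minq <- min(methods::as(quals, "IntegerList"))
    keep <- minq >= min_quality & !grepl("N", reads, fixed = TRUE)
    reads <- reads[keep]
  }
  n_qual <- length(reads)
  reads <- trim_adaptor(reads, adaptor)
  keep <- size_filter(reads, min_len, max_len)
  out <- reads[keep]
  list(reads = out,
       summary = tibble(total_reads = n_raw,
                        total_trimmed_reads = n_qual,
                        total_size_filtered_reads = length(out)))
}

#' Summarize one sample's preprocessing chain
#'
#' @param sample_id Sample identifier.
#' @param total_reads,total_trimmed_reads,total_size_filtered_reads,unique_reads
#'   Read counts along the preprocessing chain.
#' @return A one-row tibble; errors if the count chain is not monotone
#'   (`unique <= size-filtered <= trimmed <= total`).
#' @export
summarize_sample <- function(sample_id, total_reads, total_trimmed_reads,
                             total_size_filtered_reads, unique_reads) {
  assert_that(unique_reads <= total_size_filtered_reads &&
                total_size_filtered_reads <= total_trimmed_reads &&
                total_trimmed_reads <= total_reads,
              "count chain must satisfy unique <= filtered <= trimmed <= total")
  tibble(sample_id = sample_id, total_reads = total_reads,
         total_trimmed_reads = total_trimmed_reads,
         total_size_filtered_reads = total_size_filtered_reads,
         unique_reads = unique_reads)
}

#' Preprocess all libraries of a study
#'
#' Runs [preprocess_fastq()] over every library in a manifest and collapses
#' the surviving reads into unique reads with per-sample counts.
#'
#' @param manifest A tibble with columns `sample_id`, `tissue`, `fastq`.
#' @param ... Passed on to [preprocess_fastq()].
#' @return A list with `unique_reads` (see [collapse_reads()]) and
#'   `summaries` (one row per sample: sample id, tissue, read-count chain and
#'   `unique_reads`).
#' @export
preprocess_libraries <- function(manifest, ...) {
  per_sample <- purrr::map(seq_len(nrow(manifest)), function(i) {
    preprocess_fastq(manifest$fastq[i], ...)
  })
  names(per_sample) <- manifest$sample_id
  unique_reads <- collapse_reads(purrr::map(per_sample, "reads"))
  summaries <- purrr::imap(per_sample, function(x, sid) {
    mutate(x$summary, sample_id = sid,
           unique_reads = sum(unique_reads[[sid]] > 0))
  }) |>
    bind_rows() |>
    left_join(manifest[, c("sample_id", "tissue")], by = "sample_id") |>
    select("sample_id", "tissue", "total_reads", "total_trimmed_reads",
           "total_size_filtered_reads", "unique_reads")
  list(unique_reads = unique_reads, summaries = summaries)
}

#' Write collapsed unique reads as FASTA
#'
#' Headers follow the `>id_xCOUNT` convention used by read-collapsing small
#' RNA tools, with `COUNT` the total count across samples.
#'
#' @param unique_reads Tibble from [collapse_reads()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(unique_reads, path) {
  ids <- sprintf("r%06d_x%d", seq_len(nrow(unique_reads)), unique_reads$total)
  x <- Biostrings::DNAStringSet(setNames(unique_reads$sequence, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
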