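# Homology classification: local alignment with Karlin-Altschul E-values,
# conserved-family assignment, repeat and ncRNA screens, novel validation.

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman dynamic programming with affine gaps (a gap of length L
#' costs `gap_open + (L - 1) * gap_extend`). Traceback is deterministic,
#' breaking ties diagonal > up > left.
#'
#' @param query,subject Nucleotide strings (RNA normalized to DNA).
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   +1/-2/-5/-2).
#' @return A list: `score`, `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive aligned spans), `identity` (percent over aligned columns),
#'   `ncol` (aligned columns).
#' @export
smith_waterman <- function(query, subject, match = 1, mismatch = -2,
                           gap_open = -5, gap_extend = -2) {
  assert_that(nchar(query) > 0 && nchar(subject) > 0,
              "query and subject must be non-empty")
  sw_align_cpp(norm_dna(query), norm_dna(subject), match, mismatch,
               gap_open, gap_extend)
}

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' `lambda` solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` under uniform
#' base frequencies (root-finding). `K` is taken from the standard
#' tabulation for the default +1/-2 DNA scheme (0.621) and falls back to a
#' conservative 0.3 otherwise; gapped scores are treated with the same
#' parameters, a documented approximation.
#'
#' @param match,mismatch Match/mismatch scores.
#' @param K Optional override of the K parameter.
#' @return List with `lambda` and `K`.
#' @export
karlin_params <- function(match = 1, mismatch = -2, K = NULL) {
  assert_that(match > 0 && mismatch < 0,
              "need a positive match and negative mismatch score")
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  if (is.null(K)) {
    K <- if (match == 1 && mismatch == -2) 0.621 else 0.3
  }
  list(lambda = lambda, K = K)
}

#' Karlin-Altschul E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' database of length `n`.
#'
#' @param score Alignment score.
#' @param query_len,db_len Query and database lengths (nt, both > 0).
#' @param params A [karlin_params()] list.
#' @return E-value (numeric, > 0).
#' @export
evalue <- function(score, query_len, db_len, params = karlin_params()) {
  assert_that(query_len > 0 && db_len > 0,
              "query_len and db_len must be positive")
  params$K * query_len * db_len * exp(-params$lambda * score)
}

# smallest integer score whose E-value is at or below the threshold
score_for_evalue <- function(e_threshold, query_len, db_len,
                             params = karlin_params()) {
  ceiling(log(params$K * query_len * db_len / e_threshold) / params$lambda)
}

# family token of a miRBase-style hairpin identifier, e.g.
# "dre-mir-212" -> "212", "dre-let-7a" -> "let-7a"
db_family <- function(id) {
  id <- sub("^[A-Za-z]{3,4}-", "", id)
  ifelse(startsWith(id, "let-"), id, sub("^(mir|miR)-", "", id))
}

#' Classify candidates as conserved-family orthologs
#'
#' Aligns each candidate precursor against every stem-loop in the hairpin
#' reference; the best hit with E-value at or below `e_threshold` assigns
#' the candidate to that hit's family (parsed from the miRBase-style
#' identifier). Candidates without a qualifying hit enter the novel track.
#'
#' @param candidates Tibble with `candidate_id` and `sequence` columns.
#' @param hairpin_db A named `DNAStringSet` (or named character vector) of
#'   reference stem-loops with family-coded identifiers.
#' @param e_threshold Significance threshold (inclusive).
#' @param params [karlin_params()] for the scheme in use.
#' @return Tibble: `candidate_id`, `family` (`NA` when unclassified),
#'   `best_hit`, `hit_score`, `hit_evalue`, `hit_identity`.
#' @export
classify_conserved <- function(candidates, hairpin_db, e_threshold = 1e-7,
                               params = karlin_params()) {
  if (!is.character(hairpin_db)) hairpin_db <- as.character(hairpin_db)
  if (length(hairpin_db) == 0) {
    warning("empty hairpin reference: all candidates routed to the novel track")
    return(tibble(candidate_id = candidates$candidate_id,
                  family = NA_character_, best_hit = NA_character_,
                  hit_score = NA_real_, hit_evalue = NA_real_,
                  hit_identity = NA_real_))
  }
  db_len <- sum(nchar(hairpin_db))
  purrr::map(seq_len(nrow(candidates)), function(i) {
    q <- candidates$sequence[i]
    best <- NULL
    for (k in seq_along(hairpin_db)) {
      a <- smith_waterman(q, hairpin_db[[k]])
      if (is.null(best) || a$score > best$score) {
        best <- a
        best$name <- names(hairpin_db)[k]
      }
    }
    e <- evalue(best$score, nchar(q), db_len, params)
    tibble(candidate_id = candidates$candidate_id[i],
           family = if (e <= e_threshold) db_family(best$name) else NA_character_,
           best_hit = best$name, hit_score = best$score, hit_evalue = e,
           hit_identity = best$identity)
  }) |> bind_rows()
}

#' Count genomic loci of a candidate and screen out repeats
#'
#' Scans the candidate sequence against both strands of the genome,
#' collects positions whose best local alignment score corresponds to an
#' E-value at or below `e_threshold` (database size: both strands), merges
#' nearby hit positions into loci, and keeps the candidate only when it
#' maps to at most `max_hits` loci. Multi-locus candidates are interspersed
#' or tandem repeat suspects.
#'
#' @param sequence Candidate precursor sequence.
#' @param index A `mirdisc_index` (or `DNAStringSet` genome).
#' @param e_threshold Significance threshold per locus.
#' @param max_hits Maximum allowed locus count (kept iff `<= max_hits`).
#' @param params [karlin_params()].
#' @return List: `locus_count`, `keep`.
#' @export
repeat_screen <- function(sequence, index, e_threshold = 1e-6, max_hits = 5,
                          params = karlin_params()) {
  if (!inherits(index, "mirdisc_index")) index <- build_index(index)
  q <- norm_dna(sequence)
  m <- nchar(q)
  n <- 2 * sum(index$contig_len)
  smin <- score_for_evalue(e_threshold, m, n, params)
  n_loci <- 0L
  for (ci in seq_along(index$genome)) {
    L <- index$contig_len[[ci]]
    pos <- integer(0)
    for (strand in c("+", "-")) {
      subject <- as.character(
        if (strand == "+") index$genome[[ci]] else index$rc[[ci]])
      cm <- sw_scan_cpp(q, subject, 1, -2, -5, -2)
      hit <- which(cm >= smin)
      # project to genomic coordinates: a hairpin hits its own locus on both
      # strands (its reverse complement is hairpin-like), so strand-specific
      # hits at one locus must merge into a single locus
      if (strand == "-") hit <- L - hit + 1L
      pos <- c(pos, hit)
    }
    if (length(pos) == 0) next
    pos <- sort(pos)
    # merge hit positions closer than the query length into one locus
    n_loci <- n_loci + sum(diff(pos) > m) + 1L
  }
  list(locus_count = n_loci, keep = n_loci <= max_hits)
}

#' Screen candidates against other non-coding RNA databases
#'
#' A candidate whose precursor (or mature sequences) hits the screen
#' database at or below `e_threshold` is considered another kind of small
#' RNA and excluded. An empty or `NULL` database keeps everything.
#'
#' @param sequence Candidate precursor sequence.
#' @param matures Optional character vector of mature sequences to screen
#'   alongside the precursor.
#' @param screen_db Named `DNAStringSet` / character vector, or `NULL`.
#' @param e_threshold Significance threshold.
#' @param params [karlin_params()].
#' @return List: `keep`, `best_evalue`, `best_hit`.
#' @export
ncrna_screen <- function(sequence, matures = character(0), screen_db = NULL,
                         e_threshold = 1e-6, params = karlin_params()) {
  if (is.null(screen_db) || length(screen_db) == 0) {
    return(list(keep = TRUE, best_evalue = NA_real_, best_hit = NA_character_))
  }
  if (!is.character(screen_db)) screen_db <- as.character(screen_db)
  db_len <- sum(nchar(screen_db))
  queries <- c(sequence, matures[!is.na(matures)])
  best_e <- Inf
  best_hit <- NA_character_
  for (q in queries) {
    for (k in seq_along(screen_db)) {
      a <- smith_waterman(q, screen_db[[k]])
      e <- evalue(a$score, nchar(q), db_len, params)
      if (e < best_e) {
        best_e <- e
        best_hit <- names(screen_db)[k] %||% as.character(k)
      }
    }
  }
  list(keep = best_e > e_threshold, best_evalue = best_e, best_hit = best_hit)
}

#' Validate a putative novel miRNA
#'
#' The novel-acceptance cascade: the gene must be detected in at least two
#' independent samples, reads must match the expected mature products from
#' both arms perfectly, and the 5' ends of the mature-arm reads must be
#' consistently processed (more than `min_consistency` of them sharing the
#' modal 5' start).
#'
#' @param n_samples_detected Samples with at least one perfectly matching
#'   mature read.
#' @param has_5p_reads,has_3p_reads Perfect mature matches on each arm.
#' @param five_prime_consistency Fraction of mature-arm reads sharing the
#'   modal 5' start.
#' @param genome_locus_count Loci in the genome (reported, not re-tested).
#' @param screens_passed Repeat and ncRNA screens passed (candidates are
#'   expected to have passed them before validation).
#' @param min_consistency Threshold on `five_prime_consistency` (exclusive).
#' @return One-row tibble mirroring the inputs plus `verdict`.
#' @export
validate_novel <- function(n_samples_detected, has_5p_reads, has_3p_reads,
                           five_prime_consistency, genome_locus_count = NA,
                           screens_passed = TRUE, min_consistency = 0.5) {
  tibble(
    n_samples_detected = n_samples_detected,
    has_5p_reads = has_5p_reads, has_3p_reads = has_3p_reads,
    five_prime_consistency = five_prime_consistency,
    genome_locus_count = genome_locus_count,
    screens_passed = screens_passed,
    verdict = n_samples_detected >= 2 & has_5p_reads & has_3p_reads &
      five_prime_consistency > min_consistency & screens_passed
  )
}
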