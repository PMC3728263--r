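# Secondary structure: stacking-aware Nussinov folding, hairpin geometry
# classification and dinucleotide shuffling for permutation controls.

#' Fold a sequence into its maximum-weight nested secondary structure
#'
#' Dynamic-programming fold that maximizes total base-pair weight (GC = 3,
#' AU = 2, GU = 1) plus a +1 bonus for every stacked pair, over nested
#' (pseudoknot-free) structures with hairpin loops of at least 3 nt.
#' Traceback is deterministic, breaking ties toward 5'-most pairing. This is
#' a self-contained stability score, not a thermodynamic free energy; an
#' external thermodynamic folder can be swapped in behind the same contract.
#'
#' @param sequence A nucleotide string (DNA or RNA alphabet; `U` is treated
#'   as `T`). Length at most 500 nt.
#' @return An object of class `mirdisc_fold`: a list with `sequence`
#'   (normalized), `fold_score`, `pairs` (integer vector, 0 = unpaired,
#'   otherwise 1-based partner) and `dotbracket`.
#' @examples
#' fold("GGGAAACCC")$fold_score  # 3 GC pairs + 2 stacking bonuses = 11
#' @export
fold <- function(sequence) {
  assert_that(length(sequence) == 1 && is.character(sequence),
              "sequence must be a single string")
  seq <- norm_dna(sequence)
  assert_that(!grepl("[^ACGT]", seq),
              "sequence contains a non-ACGU symbol")
  assert_that(nchar(seq) <= 500, "sequence longer than 500 nt")
  res <- nussinov_fold_cpp(seq)
  pairs <- res$pairs
  db <- rep(".", nchar(seq))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  structure(list(sequence = seq, fold_score = res$score, pairs = pairs,
                 dotbracket = paste(db, collapse = "")),
            class = "mirdisc_fold")
}

#' @export
print.mirdisc_fold <- function(x, ...) {
  cat("<mirdisc_fold> score", x$fold_score, "\n")
  cat(x$sequence, "\n")
  cat(x$dotbracket, "\n")
  invisible(x)
}

#' Test whether a folded window is a miRNA-like hairpin
#'
#' A structure qualifies when its dominant helix forms a single stem-loop:
#' the fraction of base pairs nesting around the best single loop center is
#' at least `min_stem_fraction`, the mature lies on one arm (at least 70%
#' of its paired bases must pair in one direction, downstream for the 5p
#' arm, upstream for the 3p arm; a loop-centered mature pairs both ways and
#' is rejected), and at least 60% of the mature bases are paired.
#'
#' @param structure A `mirdisc_fold` object.
#' @param mature_span Integer vector `c(start, end)`, 1-based inclusive
#'   positions of the mature sequence within the folded window.
#' @param min_stem_fraction Minimum fraction of pairs belonging to the
#'   dominant stem.
#' @param min_paired Minimum fraction of mature bases that must be paired.
#' @param region Optional `c(start, end)` restricting the stem-loop
#'   assessment to a subregion (e.g. the precursor-sized span of an excised
#'   window, so that base pairs formed entirely by flanking sequence do not
#'   dilute the dominant stem). Pairs with either end outside the region
#'   are ignored for the geometry; the mature span must lie inside it.
#' @return A list with `is_hairpin` (logical) and `geometry` (a one-row
#'   tibble with the arm and loop spans, mature arm, paired fraction and
#'   dominant-stem fraction; all-`NA` spans when no pairs exist).
#' @export
is_hairpin <- function(structure, mature_span, min_stem_fraction = 0.7,
                       min_paired = 0.6, region = NULL) {
  stopifnot(inherits(structure, "mirdisc_fold"))
  n <- nchar(structure$sequence)
  assert_that(mature_span[1] >= 1 && mature_span[2] <= n &&
                mature_span[1] <= mature_span[2],
              "mature_span outside the folded sequence")
  p <- structure$pairs
  i <- which(p > seq_along(p))
  j <- p[i]
  if (!is.null(region)) {
    region <- c(max(1L, region[1]), min(n, region[2]))
    keep <- i >= region[1] & j <= region[2]
    i <- i[keep]
    j <- j[keep]
  }
  empty_geom <- tibble::new_tibble(list(
    arm5_start = NA_integer_, arm5_end = NA_integer_,
    loop_start = NA_integer_, loop_end = NA_integer_,
    arm3_start = NA_integer_, arm3_end = NA_integer_,
    mature_arm = NA_character_, paired_fraction = 0,
    stem_fraction = 0), nrow = 1L)
  if (length(i) == 0) {
    return(list(is_hairpin = FALSE, geometry = empty_geom))
  }
  # best single loop center: point (between c and c+1) covered by most pairs
  cov <- integer(n)
  for (k in seq_along(i)) {
    cov[i[k]:(j[k] - 1L)] <- cov[i[k]:(j[k] - 1L)] + 1L
  }
  ctr <- which.max(cov)
  spanning <- i <= ctr & j > ctr
  stem_fraction <- mean(spanning)
  si <- i[spanning]; sj <- j[spanning]
  arm5 <- c(min(si), max(si))
  arm3 <- c(min(sj), max(sj))
  loop <- c(arm5[2] + 1L, arm3[1] - 1L)
  # arm placement by pairing direction: a mature on the 5p arm pairs
  # predominantly with partners downstream of itself, a 3p-arm mature with
  # partners upstream; a loop-centered mature pairs both ways. This is
  # robust to spurious side branches of the maximum-pairing fold.
  mat_pos <- mature_span[1]:mature_span[2]
  partners <- p[mat_pos]
  paired_fraction <- mean(partners > 0)
  q <- partners[partners > 0]
  n_right <- sum(q > mature_span[2])
  n_left <- sum(q < mature_span[1])
  mature_arm <- if (length(q) == 0) {
    NA_character_
  } else if (n_right / length(q) >= 0.7) {
    "5p"
  } else if (n_left / length(q) >= 0.7) {
    "3p"
  } else {
    NA_character_
  }
  geom <- tibble::new_tibble(list(
    arm5_start = arm5[1], arm5_end = arm5[2],
    loop_start = loop[1], loop_end = loop[2],
    arm3_start = arm3[1], arm3_end = arm3[2],
    mature_arm = mature_arm, paired_fraction = paired_fraction,
    stem_fraction = stem_fraction), nrow = 1L)
  ok <- stem_fraction >= min_stem_fraction && !is.na(mature_arm) &&
    paired_fraction >= min_paired
  list(is_hairpin = ok, geometry = geom)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Eulerian-path shuffle that returns a random sequence with exactly the
#' same mononucleotide and dinucleotide counts as the input. Randomness is
#' drawn from R's RNG, so results are reproducible under [set.seed()].
#'
#' @param sequence A nucleotide string of length >= 2.
#' @return A shuffled nucleotide string (uppercase DNA alphabet).
#' @export
shuffle_dinucleotide <- function(sequence) {
  seq <- norm_dna(sequence)
  assert_that(nchar(seq) >= 2, "sequence must have length >= 2")
  dinuc_shuffle_cpp(seq)
}

# dinucleotide count table, used by tests and internal assertions
dinucleotide_counts <- function(sequence) {
  seq <- norm_dna(sequence)
  n <- nchar(seq)
  if (n < 2) return(table(character(0)))
  di <- substring(seq, 1:(n - 1), 2:n)
  table(di)
}
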