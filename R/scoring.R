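# Candidate scoring: hairpin stability z-score plus Dicer-consistent read
# statistics, and permutation calibration of the score cutoff to a target
# signal-to-noise ratio.

#' Default scoring weights
#'
#' Weights of the four score components: structure z-score (`w_s`), fraction
#' of 5'-consistent reads (`w_f`), log2 consistent read count (`w_r`) and
#' the star-read indicator (`w_star`).
#'
#' @param w_s,w_f,w_r,w_star Component weights.
#' @return Named list of weights.
#' @export
score_weights <- function(w_s = 1, w_f = 3, w_r = 1, w_star = 2) {
  list(w_s = w_s, w_f = w_f, w_r = w_r, w_star = w_star)
}

# Partition read evidence of one candidate window by hairpin geometry and
# compute the read-derived score components. Reads are the stack members in
# window coordinates: tibble(sequence, wstart, wend, count).
partition_evidence <- function(reads, geometry, tol = 2L) {
  a5 <- c(geometry$arm5_start, geometry$arm5_end)
  a3 <- c(geometry$arm3_start, geometry$arm3_end)
  loop <- c(geometry$loop_start, geometry$loop_end)
  p5 <- reads$wstart  # 5' end in window coordinates (window reads 5'->3')
  mid <- (reads$wstart + reads$wend) / 2
  arm <- dplyr::case_when(
    mid <= a5[2] + tol ~ "5p",
    mid >= a3[1] - tol ~ "3p",
    TRUE ~ "loop"
  )
  consistent <- rep(FALSE, nrow(reads))
  modal <- list(`5p` = NA_integer_, `3p` = NA_integer_)
  mature <- list(`5p` = NA_character_, `3p` = NA_character_)
  for (a in c("5p", "3p")) {
    sel <- arm == a
    if (!any(sel)) next
    agg <- tapply(reads$count[sel], p5[sel], sum)
    m <- as.integer(names(agg)[which.max(agg)])
    modal[[a]] <- m
    consistent[sel] <- abs(p5[sel] - m) <= tol
    on_modal <- sel & p5 == m
    mat <- reads[on_modal, ]
    mature[[a]] <- mat$sequence[which.max(mat$count)]
  }
  total <- sum(reads$count)
  n5 <- sum(reads$count[arm == "5p"])
  n3 <- sum(reads$count[arm == "3p"])
  nl <- sum(reads$count[arm == "loop"])
  ncons <- sum(reads$count[consistent])
  list(n5p = n5, n3p = n3, n_loop = nl,
       n_inconsistent = total - ncons - nl,
       f_consistent = ncons / total, n_consistent = ncons,
       star = n5 > 0 && n3 > 0,
       mature5p = mature[["5p"]], mature3p = mature[["3p"]],
       modal5p_5p = modal[["5p"]], modal5p_3p = modal[["3p"]],
       consistent = consistent, arm = arm)
}

# Convert stack member alignments (genomic) to window coordinates.
members_to_window <- function(members, cand) {
  n <- nrow(members)
  if (cand$strand == "+") {
    tibble::new_tibble(list(sequence = members$sequence,
                            wstart = members$start - cand$start + 1L,
                            wend = members$end - cand$start + 1L,
                            count = members$count), nrow = n)
  } else {
    tibble::new_tibble(list(sequence = members$sequence,
                            wstart = cand$end - members$end + 1L,
                            wend = cand$end - members$start + 1L,
                            count = members$count), nrow = n)
  }
}

# Precursor-sized hairpin assessment region of a candidate window,
# anchored at the putative mature on the hypothesized arm; pairs formed
# entirely by the far excision flank are excluded from the stem-loop
# geometry.
hairpin_region <- function(mature_start, mature_end, arm_hypothesis,
                           max_precursor = 80L) {
  if (arm_hypothesis == "5p") {
    c(mature_start - 5L, mature_start + max_precursor - 1L)
  } else {
    c(mature_end - max_precursor + 1L, mature_end + 5L)
  }
}

# Null distribution of fold scores for a window: fold n dinucleotide
# shuffles. Because a shuffle preserves dinucleotide composition, the same
# null applies to any shuffle of the window and is computed once per window.
struct_null <- function(sequence, n_shuffles = 25) {
  s <- vapply(seq_len(n_shuffles),
              function(i) fold(shuffle_dinucleotide(sequence))$fold_score,
              numeric(1))
  c(mean = mean(s), sd = max(sd(s), 1e-6))
}

# memoized fold / null moments: identical windows recur across samples, and
# both functions are deterministic per sequence (the null moments depend
# only on dinucleotide composition), so results are shared via an
# environment cache
cached_fold <- function(sequence, cache = NULL) {
  if (is.null(cache)) return(fold(sequence))
  key <- paste0("f.", sequence)
  v <- cache[[key]]
  if (is.null(v)) {
    v <- fold(sequence)
    cache[[key]] <- v
  }
  v
}

cached_null <- function(sequence, n_shuffles, cache = NULL) {
  if (is.null(cache)) return(struct_null(sequence, n_shuffles))
  key <- paste0("n.", sequence)
  v <- cache[[key]]
  if (is.null(v)) {
    v <- struct_null(sequence, n_shuffles)
    cache[[key]] <- v
  }
  v
}

#' Score candidate precursor windows
#'
#' Folds every candidate window, keeps those classified as hairpins with the
#' stack on one arm, and computes the total score
#' `w_s * z_struct + w_f * f_consistent + w_r * log2(1 + n_consistent) +
#' w_star * [star reads present]`, where `z_struct` is the fold score's
#' z-score against `n_shuffles` dinucleotide shuffles of the window,
#' `f_consistent` is the count-weighted fraction of reads whose 5' end lies
#' within +/- 2 nt of their arm's modal 5' end, `n_consistent` the
#' consistent read count, and the star indicator is set when both arms carry
#' at least one read. Mature 5p/3p sequences are the modal reads per arm.
#'
#' @param candidates Tibble from [excise_candidates()].
#' @param weights A [score_weights()] list.
#' @param n_shuffles Shuffles for the structure z-score null.
#' @param hairpin_args Named list passed to [is_hairpin()].
#' @return The candidate tibble with columns `fold_score`, `hairpin_ok`,
#'   `z_struct`, `f_consistent`, `n_consistent`, `star`, `mature5p`,
#'   `mature3p`, counts per partition, `total_score`, plus the cached null
#'   moments `null_mean`, `null_sd` and a `geometry` list-column.
#'   Non-hairpin candidates keep `total_score = -Inf`.
#' @export
score_candidates <- function(candidates, weights = score_weights(),
                             n_shuffles = 25, hairpin_args = list(),
                             cache = NULL) {
  assert_that(all(candidates$total_count >= 1),
              "candidates must carry read evidence")
  out <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    f <- cached_fold(cand$sequence, cache)
    reg <- hairpin_region(cand$mature_start, cand$mature_end,
                          cand$arm_hypothesis)
    hp <- do.call(is_hairpin,
                  c(list(f, c(cand$mature_start, cand$mature_end)),
                    hairpin_args, list(region = reg)))
    row <- tibble(fold_score = f$fold_score, hairpin_ok = hp$is_hairpin,
                  null_mean = NA_real_, null_sd = NA_real_,
                  z_struct = NA_real_, f_consistent = NA_real_,
                  n_consistent = NA_real_, star = NA,
                  n5p = NA_real_, n3p = NA_real_, n_loop = NA_real_,
                  n_inconsistent = NA_real_,
                  mature5p = NA_character_, mature3p = NA_character_,
                  total_score = -Inf, geometry = list(hp$geometry))
    if (!hp$is_hairpin) return(row)
    null <- cached_null(cand$sequence, n_shuffles, cache)
    reads <- members_to_window(cand$members[[1]], cand)
    ev <- partition_evidence(reads, hp$geometry)
    z <- (f$fold_score - null["mean"]) / null["sd"]
    total <- weights$w_s * z + weights$w_f * ev$f_consistent +
      weights$w_r * log2(1 + ev$n_consistent) + weights$w_star * ev$star
    row$null_mean <- null["mean"]; row$null_sd <- null["sd"]
    row$z_struct <- z; row$f_consistent <- ev$f_consistent
    row$n_consistent <- ev$n_consistent; row$star <- ev$star
    row$n5p <- ev$n5p; row$n3p <- ev$n3p; row$n_loop <- ev$n_loop
    row$n_inconsistent <- ev$n_inconsistent
    row$mature5p <- ev$mature5p; row$mature3p <- ev$mature3p
    row$total_score <- unname(total)
    row
  }) |> bind_rows()
  bind_cols(candidates, out)
}

# Rescore one permuted control: shuffle the window, refold, re-check the
# hairpin gate, reuse the cached structure null and read components.
permuted_score <- function(cand, weights, hairpin_args = list()) {
  seq <- shuffle_dinucleotide(cand$sequence)
  f <- fold(seq)
  reg <- hairpin_region(cand$mature_start, cand$mature_end,
                        cand$arm_hypothesis)
  hp <- do.call(is_hairpin,
                c(list(f, c(cand$mature_start, cand$mature_end)),
                  hairpin_args, list(region = reg)))
  if (!hp$is_hairpin) return(-Inf)
  z <- (f$fold_score - cand$null_mean) / cand$null_sd
  weights$w_s * z + weights$w_f * cand$f_consistent +
    weights$w_r * log2(1 + cand$n_consistent) + weights$w_star * cand$star
}

#' Calibrate the score cutoff against permuted controls
#'
#' For each of `n_rounds` rounds, every scored candidate window is
#' dinucleotide-shuffled (read positions retained) and rescored, and the
#' signal-to-noise ratio `SNR(c) = n_real(score >= c) / mean n_permuted
#' (score >= c)` is evaluated on a grid of percentiles of the real scores
#' (1% steps). The cutoff is the smallest grid value whose SNR reaches
#' `target_snr`; the permuted-survivor mean is floored at `1 / n_rounds`
#' when no permuted control survives.
#'
#' @param scored Tibble from [score_candidates()] (hairpin-passing rows are
#'   used).
#' @param n_rounds Permutation rounds.
#' @param target_snr Target signal-to-noise ratio.
#' @param weights A [score_weights()] list (must match the scoring call).
#' @param hairpin_args Named list passed to [is_hairpin()].
#' @return An object of class `mirdisc_calibration`: list with `cutoff`,
#'   `snr_at_cutoff`, `warning` (TRUE when no grid value reached the
#'   target), `n_rounds`, `target_snr` and `table` (tibble of `cutoff`,
#'   `n_real`, `mean_n_permuted`, `snr`).
#' @export
calibrate_cutoff <- function(scored, n_rounds = 100, target_snr = 40,
                             weights = score_weights(),
                             hairpin_args = list()) {
  real <- scored$total_score[is.finite(scored$total_score)]
  assert_that(length(real) >= 1, "no scored candidates to calibrate on")
  cands <- scored[is.finite(scored$total_score), ]
  # vectorized permutation loop: the read components are retained, only the
  # structure z-score is recomputed on the shuffled window
  seqs <- cands$sequence
  ms <- cands$mature_start
  me <- cands$mature_end
  hyp <- cands$arm_hypothesis
  nmu <- cands$null_mean
  nsd <- cands$null_sd
  read_comp <- weights$w_f * cands$f_consistent +
    weights$w_r * log2(1 + cands$n_consistent) + weights$w_star * cands$star
  perm <- matrix(-Inf, nrow = n_rounds, ncol = nrow(cands))
  for (r in seq_len(n_rounds)) {
    for (k in seq_along(seqs)) {
      f <- fold(shuffle_dinucleotide(seqs[k]))
      hp <- do.call(is_hairpin,
                    c(list(f, c(ms[k], me[k])), hairpin_args,
                      list(region = hairpin_region(ms[k], me[k], hyp[k]))))
      if (!hp$is_hairpin) next
      perm[r, k] <- read_comp[k] +
        weights$w_s * (f$fold_score - nmu[k]) / nsd[k]
    }
  }
  grid <- unname(quantile(real, probs = seq(0, 1, by = 0.01), type = 1))
  grid <- sort(unique(grid))
  tab <- purrr::map(grid, function(cc) {
    n_real <- sum(real >= cc)
    mean_perm <- mean(rowSums(perm >= cc))
    snr <- n_real / max(mean_perm, 1 / n_rounds)
    tibble(cutoff = cc, n_real = n_real, mean_n_permuted = mean_perm,
           snr = snr)
  }) |> bind_rows()
  ok <- tab$snr >= target_snr
  warn <- !any(ok)
  cutoff <- if (warn) max(grid) else min(tab$cutoff[ok])
  if (warn) {
    warning("no cutoff reached the target signal-to-noise ratio; ",
            "using the maximum grid value")
  }
  structure(list(cutoff = cutoff,
                 snr_at_cutoff = tab$snr[match(cutoff, tab$cutoff)],
                 warning = warn, n_rounds = n_rounds,
                 target_snr = target_snr, table = tab),
            class = "mirdisc_calibration")
}

#' @export
print.mirdisc_calibration <- function(x, ...) {
  cat("<mirdisc_calibration> cutoff", format(x$cutoff, digits = 4),
      "at SNR", format(x$snr_at_cutoff, digits = 4),
      "(target", paste0(x$target_snr, ":1,"), x$n_rounds, "rounds)\n")
  invisible(x)
}

#' Call putative miRNAs from scored candidates
#'
#' Candidates scoring at or above the calibrated cutoff (inclusive) are
#' called as putative miRNAs, with the modal per-arm reads retained as their
#' mature 5p/3p assignments.
#'
#' @param scored Tibble from [score_candidates()].
#' @param calibration A `mirdisc_calibration` (or a numeric cutoff).
#' @return The called subset of `scored`.
#' @export
call_candidates <- function(scored, calibration) {
  cutoff <- if (inherits(calibration, "mirdisc_calibration")) {
    calibration$cutoff
  } else {
    calibration
  }
  filter(scored, is.finite(.data$total_score), .data$total_score >= cutoff)
}
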