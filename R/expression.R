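# Quantification and differential expression: perfect-match count matrix,
# total-count normalization, replicate correlation, negative-binomial
# one-tissue-versus-rest exact tests with BH correction, presence scan.

#' Build the miRNA-by-sample count matrix
#'
#' Counts, per gene and sample, the reads exactly equal to either mature
#' sequence. A read matching the matures of two genes counts for both.
#'
#' @param genes Tibble with `name`, `mature5p`, `mature3p` (one row per
#'   gene; duplicate names are collapsed).
#' @param unique_reads Tibble from [collapse_reads()].
#' @return Tibble: `mirna` plus one count column per sample.
#' @export
build_count_matrix <- function(genes, unique_reads) {
  samples <- setdiff(names(unique_reads), c("sequence", "total"))
  g <- distinct(genes, .data$name, .data$mature5p, .data$mature3p)
  rows <- purrr::map(seq_len(nrow(g)), function(i) {
    hit <- unique_reads$sequence %in%
      norm_dna(c(g$mature5p[i], g$mature3p[i]))
    counts <- if (any(hit)) {
      colSums(unique_reads[hit, samples, drop = FALSE])
    } else {
      setNames(rep(0, length(samples)), samples)
    }
    tibble(mirna = g$name[i], !!!as.list(counts))
  })
  bind_rows(rows)
}

#' Per-arm read counts for arm-dominance calls
#'
#' @param genes Tibble with `name`, `mature5p`, `mature3p`.
#' @param unique_reads Tibble from [collapse_reads()].
#' @return Tibble: `mirna`, `count5p`, `count3p` (totals across samples).
#' @export
arm_read_counts <- function(genes, unique_reads) {
  g <- distinct(genes, .data$name, .data$mature5p, .data$mature3p)
  purrr::map(seq_len(nrow(g)), function(i) {
    c5 <- sum(unique_reads$total[unique_reads$sequence ==
                                   norm_dna(g$mature5p[i])])
    c3 <- sum(unique_reads$total[unique_reads$sequence ==
                                   norm_dna(g$mature3p[i])])
    tibble(mirna = g$name[i], count5p = c5, count3p = c3)
  }) |> bind_rows()
}

count_matrix_samples <- function(counts) {
  setdiff(names(counts), "mirna")
}

#' Normalize a count matrix by total miRNA counts
#'
#' Size factor of a sample: its total miRNA count divided by the geometric
#' mean of all column totals (the reference scale). Normalized counts are
#' raw counts divided by the size factor, so scaling a column's raw counts
#' leaves its normalized values unchanged.
#'
#' @param counts Count tibble from [build_count_matrix()].
#' @return List: `normalized` (same shape tibble), `size_factors` (named),
#'   `ref_scale` (geometric-mean total). Zero-total columns get size factor
#'   `NA` with a warning.
#' @export
normalize_counts <- function(counts) {
  samples <- count_matrix_samples(counts)
  totals <- vapply(samples, function(s) sum(counts[[s]]), numeric(1))
  assert_that(any(totals > 0), "all-zero count matrix")
  if (any(totals == 0)) {
    warning("zero-total samples flagged with NA size factors: ",
            paste(samples[totals == 0], collapse = ", "))
  }
  ref <- exp(mean(log(totals[totals > 0])))
  sf <- ifelse(totals > 0, totals / ref, NA_real_)
  names(sf) <- samples
  normalized <- counts
  for (s in samples) normalized[[s]] <- counts[[s]] / sf[[s]]
  list(normalized = normalized, size_factors = sf, ref_scale = ref)
}

#' Pearson correlation between two replicate libraries
#'
#' @param normalized Normalized count tibble ([normalize_counts()]).
#' @param sample_a,sample_b Sample column names.
#' @param log2 Correlate on `log2(x + 1)` instead of the linear scale.
#' @return Pearson r.
#' @export
replicate_correlation <- function(normalized, sample_a, sample_b,
                                  log2 = FALSE) {
  a <- normalized[[sample_a]]
  b <- normalized[[sample_b]]
  assert_that(length(a) >= 3, "need at least 3 shared miRNAs")
  if (log2) {
    a <- log2(a + 1)
    b <- log2(b + 1)
  }
  assert_that(var(a) > 0 && var(b) > 0,
              "zero variance in a replicate column")
  cor(a, b, method = "pearson")
}

#' Rest-over-tissue log2 fold change
#'
#' Sign convention: negative values mean enrichment in the focal tissue.
#' When either mean is zero the fold change is infinite (no pseudocount is
#' added); `is.infinite()` on the result flags those cases.
#'
#' @param mean_tissue,mean_rest Normalized group means.
#' @return `log2(mean_rest / mean_tissue)`.
#' @export
log2_fc_rest_over_tissue <- function(mean_tissue, mean_rest) {
  log2(mean_rest / mean_tissue)
}

# method-of-moments common dispersion over genes:
# Var(k/s) = q * mean(1/s) + alpha * q^2  =>  alpha_i = (v - m*xi) / m^2
common_dispersion <- function(counts, size_factors) {
  samples <- names(size_factors)
  xi <- mean(1 / size_factors)
  alphas <- vapply(seq_len(nrow(counts)), function(i) {
    z <- as.numeric(unlist(counts[i, samples])) / size_factors
    m <- mean(z)
    if (m <= 0) return(NA_real_)
    (var(z) - m * xi) / m^2
  }, numeric(1))
  alphas <- alphas[!is.na(alphas)]
  if (length(alphas) == 0) return(0)
  max(0, median(alphas))
}

# DESeq-style two-group exact test on summed counts, conditional on the
# total; NB moments matched per group, binomial (Poisson) fallback when the
# dispersion is zero.
nb_exact_test <- function(kA, kB, sA, s2A, sB, s2B, alpha) {
  S <- kA + kB
  if (S == 0) return(1)
  q <- S / (sA + sB)
  muA <- q * sA
  muB <- q * sB
  a <- 0:S
  if (alpha <= 1e-12) {
    probs <- dbinom(a, S, muA / (muA + muB))
  } else {
    sizeA <- muA^2 / (alpha * q^2 * s2A)
    sizeB <- muB^2 / (alpha * q^2 * s2B)
    probs <- dnbinom(a, mu = muA, size = sizeA) *
      dnbinom(S - a, mu = muB, size = sizeB)
  }
  tot <- sum(probs)
  if (tot <= 0) return(1)
  pobs <- probs[kA + 1]
  min(1, sum(probs[probs <= pobs + 1e-12 * pobs]) / tot)
}

#' One-tissue-versus-rest differential expression test
#'
#' Negative-binomial exact test of the focal tissue's samples against all
#' other samples, per miRNA, with total-count size factors
#' ([normalize_counts()]), a method-of-moments common dispersion shared
#' across miRNAs (per-gene dispersions are unidentifiable in a
#' one-versus-rest design with few replicates), and Benjamini-Hochberg
#' adjustment across the tested miRNAs. Fold changes are rest over tissue,
#' so tissue-enriched miRNAs get negative `log2_fc`.
#'
#' @param counts Count tibble from [build_count_matrix()].
#' @param samples Tibble mapping `sample_id` to `tissue`.
#' @param tissue Focal tissue (must have at least one sample, and at least
#'   one sample must remain in the rest group).
#' @return A tibble of class `mirdisc_de`: `mirna`, `tissue`, `mean_tissue`,
#'   `mean_rest` (normalized means), `log2_fc`, `fc_infinite`, `p_value`,
#'   `p_adj`. Attributes: `dispersion`, `method`.
#' @export
one_vs_rest_test <- function(counts, samples, tissue) {
  sample_ids <- count_matrix_samples(counts)
  grpA <- samples$sample_id[samples$tissue == tissue]
  grpA <- intersect(grpA, sample_ids)
  grpB <- setdiff(sample_ids, grpA)
  assert_that(length(grpA) >= 1,
              paste0("no samples for tissue group '", tissue, "'"))
  assert_that(length(grpB) >= 1, "no samples left in the rest group")
  norm <- normalize_counts(counts)
  sf <- norm$size_factors
  alpha <- common_dispersion(counts, sf)
  sA <- sum(sf[grpA]); s2A <- sum(sf[grpA]^2)
  sB <- sum(sf[grpB]); s2B <- sum(sf[grpB]^2)
  res <- purrr::map(seq_len(nrow(counts)), function(i) {
    kA <- sum(as.numeric(unlist(counts[i, grpA])))
    kB <- sum(as.numeric(unlist(counts[i, grpB])))
    mt <- kA / sA
    mr <- kB / sB
    lfc <- log2_fc_rest_over_tissue(mt, mr)
    tibble(mirna = counts$mirna[i], tissue = tissue,
           mean_tissue = mt, mean_rest = mr,
           log2_fc = lfc, fc_infinite = is.infinite(lfc) | is.nan(lfc),
           p_value = nb_exact_test(kA, kB, sA, s2A, sB, s2B, alpha))
  }) |> bind_rows()
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  structure(res, class = c("mirdisc_de", class(res)),
            dispersion = alpha,
            method = if (alpha <= 1e-12) "poisson" else "nb")
}

#' Scan for tissue-restricted miRNAs by read presence
#'
#' Presence means at least one read perfectly matching a mature sequence in
#' at least one sample of a tissue. miRNAs present in exactly one tissue
#' are flagged as candidate tissue-specific genes.
#'
#' @param counts Count tibble from [build_count_matrix()].
#' @param samples Tibble mapping `sample_id` to `tissue`.
#' @return Tibble: `mirna`, `tissues` (list-column of tissues with
#'   presence), `n_tissues`, `specific_tissue` (`NA` unless present in
#'   exactly one tissue).
#' @export
tissue_presence_scan <- function(counts, samples) {
  sample_ids <- count_matrix_samples(counts)
  tis <- setNames(samples$tissue, samples$sample_id)[sample_ids]
  purrr::map(seq_len(nrow(counts)), function(i) {
    present <- unique(unname(tis[as.numeric(unlist(counts[i, sample_ids])) >= 1]))
    tibble(mirna = counts$mirna[i], tissues = list(present),
           n_tissues = length(present),
           specific_tissue = if (length(present) == 1) present else
             NA_character_)
  }) |> bind_rows()
}
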