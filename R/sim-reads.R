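# Simulation of Dicer-processed reads and per-sample FASTQ libraries.

#' Simulate Dicer-processed reads from one hairpin gene
#'
#' Draws reads from the 5p mature, 3p mature and loop regions of a planted
#' precursor. The 5p:3p draw ratio follows `arm_ratio`; each mature read's
#' 5' start offset is drawn from the jitter distribution (the evidence
#' signature of consistent Dicer processing), with a small amount of 3'
#' length heterogeneity. All reads are 18-26 nt. Randomness comes from R's
#' RNG, so wrap calls in [set.seed()] for reproducibility.
#'
#' @param gene A list describing the precursor: `precursor` plus 1-based
#'   mature coordinates `m5_start`, `m5_end`, `m3_start`, `m3_end` (as
#'   produced by the simulator's hairpin generator).
#' @param n_reads Number of reads to draw (0 gives an empty vector).
#' @param arm_ratio Expected ratio of 5p to 3p reads (> 0).
#' @param jitter Probability vector over absolute 5' offsets 0, 1, 2 nt;
#'   offset sign is drawn uniformly.
#' @param loop_fraction Fraction of reads drawn from the loop region.
#' @return Character vector of read sequences.
#' @export
simulate_dicer_reads <- function(gene, n_reads, arm_ratio,
                                 jitter = c(0.8, 0.15, 0.05),
                                 loop_fraction = 0.02) {
  assert_that(n_reads >= 0, "n_reads must be >= 0")
  assert_that(arm_ratio > 0, "arm_ratio must be > 0")
  assert_that(abs(sum(jitter) - 1) < 1e-8, "jitter probabilities must sum to 1")
  if (n_reads == 0) return(character(0))
  prec <- gene$precursor
  plen <- nchar(prec)
  p5 <- (1 - loop_fraction) * arm_ratio / (1 + arm_ratio)
  p3 <- (1 - loop_fraction) / (1 + arm_ratio)
  src <- sample(c("5p", "3p", "loop"), n_reads, replace = TRUE,
                prob = c(p5, p3, loop_fraction))
  off_mag <- sample(0:2, n_reads, replace = TRUE, prob = jitter)
  off <- off_mag * sample(c(-1L, 1L), n_reads, replace = TRUE)
  len_jit <- sample(c(-1L, 0L, 1L), n_reads, replace = TRUE,
                    prob = c(0.1, 0.8, 0.1))
  m_start <- ifelse(src == "5p", gene$m5_start, gene$m3_start)
  m_len <- ifelse(src == "5p", gene$m5_end - gene$m5_start + 1L,
                  gene$m3_end - gene$m3_start + 1L)
  start <- pmax(1L, m_start + off)
  len <- pmin(26L, pmax(18L, m_len + len_jit))
  is_loop <- src == "loop"
  if (any(is_loop)) {
    lo <- gene$m5_end + 1L
    hi <- gene$m3_start - 1L
    llen <- pmin(22L, sample(18:22, sum(is_loop), replace = TRUE))
    lstart <- pmax(1L, lo - 4L +
                     floor(runif(sum(is_loop)) * pmax(1, hi - lo)))
    start[is_loop] <- lstart
    len[is_loop] <- llen
  }
  end <- pmin(plen, start + len - 1L)
  substring(prec, start, end)
}

# FASTQ writer: constant Phred+33 quality 'I' (Q40)
write_fastq <- function(reads, ids, path) {
  qual <- strrep("I", nchar(reads))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), path)
}

# GRanges of the planted truth, serializable as GFF3
truth_granges <- function(truth) {
  g <- truth$genes
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    type = "miRNA_primary_transcript",
    ID = g$gene_id, Name = g$name, family = g$family,
    conserved = g$is_conserved_homolog,
    cluster_id = g$cluster_id, copy_group = g$copy_group
  )
  r <- truth$repeats
  if (nrow(r) > 0) {
    gr_rep <- GenomicRanges::GRanges(
      seqnames = r$contig,
      ranges = IRanges::IRanges(start = r$start, end = r$end),
      strand = r$strand,
      type = "repeat_region",
      ID = paste0(r$repeat_id, "_", seq_len(nrow(r))),
      Name = r$repeat_id, family = NA_character_, conserved = NA,
      cluster_id = NA_character_, copy_group = r$repeat_id
    )
    gr_genes <- suppressWarnings(c(gr_genes, gr_rep))
  }
  gr_genes
}

#' Write simulated per-sample FASTQ libraries with ground truth
#'
#' Simulates every library of the study defined by `truth$tissue_profiles`:
#' per-gene read counts are Poisson draws around the expected counts, reads
#' are generated by [simulate_dicer_reads()], background degradation reads
#' (random genome windows plus fragments of the planted ncRNA) fill the
#' library up to `config$depth`, the 3' adaptor is appended to every insert
#' and the result truncated to the fixed read length. Ground truth is
#' written as GFF3 alongside a sample manifest.
#'
#' @param genome Named `DNAStringSet` from [build_toy_genome()].
#' @param truth Truth list from [build_toy_genome()].
#' @param config The [sim_config()] used to build the genome.
#' @param out_dir Output directory (created if missing).
#' @return A tibble manifest (`sample_id`, `tissue`, `fastq`), invisibly
#'   written to `manifest.tsv`, with the truth GFF3 at `truth.gff3`.
#' @export
write_sample_libraries <- function(genome, truth, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  samples <- truth$samples
  profiles <- tidyr::pivot_wider(truth$tissue_profiles,
                                 id_cols = "sample_id",
                                 names_from = "unit_id",
                                 values_from = "expected_reads")
  contig_seqs <- as.character(genome)
  contig_len <- Biostrings::width(genome)
  ncr <- truth$ncrna_locus
  ncrna_seq <- substr(contig_seqs[[ncr$contig]], ncr$start, ncr$end)
  fastqs <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    prow <- profiles[profiles$sample_id == sid, , drop = FALSE]
    unit_ids <- setdiff(names(prow), "sample_id")
    reads <- character(0)
    for (uid in unit_ids) {
      expected <- prow[[uid]]
      n <- if (expected > 0) rpois(1, expected) else 0L
      if (n == 0) next
      u <- truth$units[[uid]]
      reads <- c(reads, simulate_dicer_reads(u$hp, n, u$arm_ratio,
                                             config$five_prime_jitter,
                                             config$loop_fraction))
    }
    n_bg <- if (config$background_rate > 0) {
      max(0L, config$depth - length(reads))
    } else {
      0L
    }
    if (n_bg > 0) {
      n_nc <- rbinom(1, n_bg, 0.2)
      n_gen <- n_bg - n_nc
      if (n_gen > 0) {
        ctg <- sample(seq_along(contig_seqs), n_gen, replace = TRUE,
                      prob = contig_len)
        len <- sample(18:26, n_gen, replace = TRUE)
        start <- 1L + floor(runif(n_gen) * (contig_len[ctg] - len))
        frag <- substring(contig_seqs[ctg], start, start + len - 1L)
        minus <- runif(n_gen) < 0.5
        if (any(minus)) frag[minus] <- revcomp(frag[minus])
        reads <- c(reads, frag)
      }
      if (n_nc > 0) {
        len <- sample(18:26, n_nc, replace = TRUE)
        start <- 1L + floor(runif(n_nc) * (nchar(ncrna_seq) - len))
        reads <- c(reads, substring(ncrna_seq, start, start + len - 1L))
      }
    }
    reads <- reads[sample.int(length(reads))]
    raw <- substr(paste0(reads, config$adaptor), 1L, config$read_length)
    fq <- file.path(out_dir, paste0(sid, ".fastq"))
    write_fastq(raw, sprintf("%s_r%06d", sid, seq_along(raw)), fq)
    fastqs[i] <- fq
  }
  manifest <- mutate(samples, fastq = fastqs)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  rtracklayer::export(truth_granges(truth), file.path(out_dir, "truth.gff3"),
                      format = "gff3")
  invisible(manifest)
}
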