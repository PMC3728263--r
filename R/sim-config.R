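#' Simulation configuration for the synthetic small RNA study
#'
#' Builds the configuration object consumed by [build_toy_genome()] and
#' [write_sample_libraries()]. The defaults define a twelve-library,
#' nine-tissue study on a ~500 kb toy genome: conserved miRNA genes (one
#' heart-restricted, a brain-enriched clustered pair duplicated on two
#' contigs, plus ubiquitously expressed families, two of them planted as
#' identical two-copy duplicates), novel genes absent from the hairpin
#' reference (one restricted to the two liver libraries), and one repeat
#' decoy hairpin planted at `repeat_copy_number` loci so that it trips the
#' multi-locus repeat screen.
#'
#' @param genome_size Total genome length in nt, split across `n_contigs`.
#' @param n_contigs Number of contigs.
#' @param n_conserved Number of conserved miRNA families planted (>= 4; the
#'   first three are the heart-only gene and the clustered brain pair).
#' @param n_novel Number of novel genes planted (>= 1; the first is the
#'   liver-restricted gene).
#' @param n_duplicated How many of the ubiquitous conserved genes are planted
#'   as identical two-copy duplicates (the clustered pair is always
#'   duplicated across two contigs in addition).
#' @param repeat_copy_number Copy number of the planted repeat decoy; must be
#'   at least 6 so the decoy exceeds the >5-locus repeat threshold.
#' @param p5p Probability that a gene is 5p-arm dominant.
#' @param dominant_ratio Read-count ratio of the dominant to the minor arm.
#' @param p_balanced Probability of a balanced (ratio 1) gene.
#' @param five_prime_jitter Probability vector over absolute 5' start offsets
#'   0, 1, 2 nt (sign drawn uniformly); must sum to 1.
#' @param loop_fraction Fraction of a gene's reads that are loop fragments.
#' @param background_rate Fraction of each library made of degradation
#'   background (random genome fragments and fragments of a planted ncRNA).
#' @param adaptor 3' adaptor sequence ligated to every read.
#' @param read_length Fixed sequencer read length in nt (insert plus adaptor
#'   read-through, truncated).
#' @param depth Reads per sample library.
#' @param db_mut_rate Upper bound of the per-base mutation rate applied to
#'   conserved precursors when writing the hairpin reference database
#'   (per-gene rate drawn uniformly from 0 to this bound).
#' @param db_n_decoys Unrelated hairpin entries added to the reference.
#' @param seed Integer seed governing every random draw.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 500000,
                       n_contigs = 20,
                       n_conserved = 10,
                       n_novel = 4,
                       n_duplicated = 2,
                       repeat_copy_number = 8,
                       p5p = 0.6,
                       dominant_ratio = 20,
                       p_balanced = 0.05,
                       five_prime_jitter = c(0.80, 0.15, 0.05),
                       loop_fraction = 0.02,
                       background_rate = 0.05,
                       adaptor = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 32,
                       depth = 50000,
                       db_mut_rate = 0.10,
                       db_n_decoys = 10,
                       seed = 42) {
  assert_that(repeat_copy_number >= 6,
              "repeat_copy_number must be >= 6 so decoys trip the repeat screen")
  assert_that(abs(sum(five_prime_jitter) - 1) < 1e-8,
              "five_prime_jitter probabilities must sum to 1")
  assert_that(length(five_prime_jitter) == 3,
              "five_prime_jitter must give probabilities for offsets 0, 1, 2")
  assert_that(depth > 0, "depth must be positive")
  assert_that(n_conserved >= 4, "need at least 4 conserved families")
  assert_that(n_novel >= 1, "need at least 1 novel gene")
  assert_that(background_rate >= 0 && background_rate < 1,
              "background_rate must be in [0, 1)")
  assert_that(nchar(adaptor) >= 2, "adaptor must be at least 2 nt")
  structure(list(
    genome_size = genome_size, n_contigs = n_contigs,
    n_conserved = n_conserved, n_novel = n_novel,
    n_duplicated = n_duplicated, repeat_copy_number = repeat_copy_number,
    p5p = p5p, dominant_ratio = dominant_ratio, p_balanced = p_balanced,
    five_prime_jitter = five_prime_jitter, loop_fraction = loop_fraction,
    background_rate = background_rate, adaptor = adaptor,
    read_length = read_length, depth = depth,
    db_mut_rate = db_mut_rate, db_n_decoys = db_n_decoys, seed = seed
  ), class = "sim_config")
}

#' Sample sheet of the simulated study
#'
#' Twelve libraries over nine tissues plus a whole-fry sample, mirroring a
#' two-individual multi-tissue small RNA study design (liver and spleen in
#' duplicate).
#'
#' @return A tibble with columns `sample_id` and `tissue`.
#' @export
sim_samples <- function() {
  tibble(
    sample_id = sprintf("S%02d", 1:12),
    tissue = c("liver", "liver", "spleen", "spleen", "kidney", "head_kidney",
               "heart", "brain", "intestine", "muscle", "gills", "whole_fry")
  )
}
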