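# Toy genome construction with planted miRNA genes, repeat decoys and a
# planted structural ncRNA, plus the matching hairpin reference database.

# Random hairpin precursor: STEM + LOOP + revcomp(STEM) with 1-3 planted
# mismatches in the 3p arm. One mismatch is forced at the stem position
# complementary to the middle of the 5p mature, a position covered by every
# jittered mature read from either arm: a perfect inverted repeat would let
# mature reads exact-match the antisense strand of their own locus, making
# the transcribed strand unidentifiable. Validated against the structure
# module so every planted precursor folds into a single stem-loop with both
# matures >= 60% paired; rejection-sampled until it does.
make_hairpin <- function(max_tries = 40) {
  for (try in seq_len(max_tries)) {
    stem_len <- sample(26:30, 1)
    loop_len <- sample(8:15, 1)
    stem <- random_dna(1, stem_len)
    loop <- random_dna(1, loop_len)
    arm3 <- revcomp(stem)
    n_extra <- sample(0:2, 1)
    pos <- unique(c(stem_len - 13L + 1L,
                    if (n_extra > 0) sample(seq_len(stem_len), n_extra)))
    for (p in pos) {
      cur <- substr(arm3, p, p)
      substr(arm3, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    precursor <- paste0(stem, loop, arm3)
    len <- nchar(precursor)
    m5 <- c(3L, 24L)
    l3 <- sample(21:22, 1)
    m3 <- c(len - 1L - l3, len - 2L)
    f <- fold(precursor)
    ok5 <- is_hairpin(f, m5)$is_hairpin
    ok3 <- is_hairpin(f, m3)$is_hairpin
    if (ok5 && ok3) {
      return(list(precursor = precursor,
                  m5_start = m5[1], m5_end = m5[2],
                  m3_start = m3[1], m3_end = m3[2]))
    }
  }
  stop("failed to construct a foldable hairpin", call. = FALSE)
}

# Draw an arm ratio (5p reads per 3p read) from the configured mixture.
draw_arm_ratio <- function(config) {
  u <- runif(1)
  if (u < config$p_balanced) return(1)
  if (runif(1) < config$p5p) config$dominant_ratio else 1 / config$dominant_ratio
}

#' Build a toy genome with planted miRNA genes and ground truth
#'
#' Plants conserved and novel hairpin genes (including identical duplicates,
#' a same-strand gene cluster replicated on two contigs, a multi-copy repeat
#' decoy and one structural ncRNA) into random contigs, and derives the
#' matching hairpin reference database: every conserved-category precursor is
#' present in the reference mutated at 0 to `db_mut_rate` of its positions
#' under a reference-species prefix, novel genes are absent.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (a named [Biostrings::DNAStringSet]),
#'   `truth` (list of tibbles: `genes` one row per planted locus, `repeats`,
#'   `tissue_profiles` with expected read counts per sample and expression
#'   unit), `hairpin_db` and `screen_db` (both `DNAStringSet`).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  contig_len <- floor(config$genome_size / config$n_contigs)
  contig_names <- sprintf("contig%03d", seq_len(config$n_contigs))
  contigs <- random_dna(config$n_contigs, contig_len)
  names(contigs) <- contig_names

  occupied <- lapply(contig_names, function(x) cbind(start = integer(0), end = integer(0)))
  names(occupied) <- contig_names
  pad <- 300L
  # planted units are kept > 10 kb apart (except within a planted cluster)
  # so that no unintended gene cluster arises by placement
  spacing <- 10500L
  place_locus <- function(len, contig = NULL, min_start = NULL) {
    for (try in seq_len(500)) {
      ctg <- if (is.null(contig)) sample(contig_names, 1) else contig
      lo <- if (is.null(min_start)) pad else max(pad, min_start)
      hi <- contig_len - len - pad
      if (hi <= lo) next
      start <- sample(lo:hi, 1)
      occ <- occupied[[ctg]]
      clash <- any(start <= occ[, "end"] + spacing &
                     (start + len - 1) >= occ[, "start"] - spacing)
      if (!clash) {
        occupied[[ctg]] <<- rbind(occ, c(start, start + len - 1L))
        return(list(contig = ctg, start = start, end = start + len - 1L))
      }
    }
    stop("genome too small to place requested genes without overlap ",
         "(genome_size = ", config$genome_size, ")", call. = FALSE)
  }

  fam_pool <- c("21", "26", "30", "100", "122", "25", "9", "142", "27", "19",
                "23", "150", "451", "727")
  conserved_fams <- c("736", "212", "132",
                      fam_pool[seq_len(config$n_conserved - 3)])

  genes <- list()
  profiles <- list()
  units <- list()   # per expression unit: hairpin + arm ratio + loci ids
  gi <- 0L

  add_locus <- function(unit_id, name, family, hp, ctg, start, strand,
                        conserved, cluster_id, copy_group) {
    gi <<- gi + 1L
    len <- nchar(hp$precursor)
    genes[[gi]] <<- tibble(
      gene_id = sprintf("g%02d", gi), unit_id = unit_id, name = name,
      family = family, contig = ctg, start = start, end = start + len - 1L,
      strand = strand, precursor = hp$precursor,
      mature5p = substr(hp$precursor, hp$m5_start, hp$m5_end),
      mature3p = substr(hp$precursor, hp$m3_start, hp$m3_end),
      is_conserved_homolog = conserved,
      cluster_id = cluster_id, copy_group = copy_group
    )
  }

  plant <- function(hp, ctg, start, strand) {
    seq <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
    substr(contigs[[ctg]], start, start + nchar(seq) - 1L) <<- seq
  }

  # --- clustered brain pair (families 212 + 132), identical copy on 2 contigs
  hp212 <- make_hairpin(); hp132 <- make_hairpin()
  cluster_contigs <- sample(contig_names, 2)
  for (k in 1:2) {
    ctg <- cluster_contigs[k]
    strand <- "+"
    len212 <- nchar(hp212$precursor); len132 <- nchar(hp132$precursor)
    span <- len212 + 4000L + len132
    loc <- place_locus(span, contig = ctg)
    s1 <- loc$start
    s2 <- loc$start + len212 + 4000L
    plant(hp212, ctg, s1, strand)
    plant(hp132, ctg, s2, strand)
    add_locus("u_mir212", "sim-mir-212", "212", hp212, ctg, s1, strand,
              TRUE, paste0("cl", k), "cg_212")
    add_locus("u_mir132", "sim-mir-132", "132", hp132, ctg, s2, strand,
              TRUE, paste0("cl", k), "cg_132")
  }
  units$u_mir212 <- list(hp = hp212, arm_ratio = config$dominant_ratio)
  units$u_mir132 <- list(hp = hp132, arm_ratio = config$dominant_ratio)

  # --- heart-restricted conserved gene (family 736)
  hp736 <- make_hairpin()
  loc <- place_locus(nchar(hp736$precursor))
  strand <- sample(c("+", "-"), 1)
  plant(hp736, loc$contig, loc$start, strand)
  add_locus("u_mir736", "sim-mir-736", "736", hp736, loc$contig, loc$start,
            strand, TRUE, NA_character_, NA_character_)
  units$u_mir736 <- list(hp = hp736, arm_ratio = config$dominant_ratio)

  # --- remaining conserved families; the first n_duplicated planted twice
  other_fams <- conserved_fams[-(1:3)]
  for (k in seq_along(other_fams)) {
    fam <- other_fams[k]
    hp <- make_hairpin()
    uid <- paste0("u_mir", fam)
    n_copies <- if (k <= config$n_duplicated) 2L else 1L
    cg <- if (n_copies > 1) paste0("cg_", fam) else NA_character_
    for (cp in seq_len(n_copies)) {
      loc <- place_locus(nchar(hp$precursor))
      strand <- sample(c("+", "-"), 1)
      plant(hp, loc$contig, loc$start, strand)
      add_locus(uid, paste0("sim-mir-", fam), fam, hp, loc$contig, loc$start,
                strand, TRUE, NA_character_, cg)
    }
    units[[uid]] <- list(hp = hp, arm_ratio = draw_arm_ratio(config))
  }

  # --- novel genes; the first is liver-restricted
  for (k in seq_len(config$n_novel)) {
    hp <- make_hairpin()
    uid <- paste0("u_novel", k)
    loc <- place_locus(nchar(hp$precursor))
    strand <- sample(c("+", "-"), 1)
    plant(hp, loc$contig, loc$start, strand)
    add_locus(uid, paste0("sim-novel-", k), NA_character_, hp, loc$contig,
              loc$start, strand, FALSE, NA_character_, NA_character_)
    units[[uid]] <- list(hp = hp, arm_ratio = draw_arm_ratio(config))
  }

  # --- repeat decoy: one hairpin at repeat_copy_number loci
  hp_rep <- make_hairpin()
  rep_loci <- list()
  for (cp in seq_len(config$repeat_copy_number)) {
    loc <- place_locus(nchar(hp_rep$precursor))
    strand <- sample(c("+", "-"), 1)
    plant(hp_rep, loc$contig, loc$start, strand)
    rep_loci[[cp]] <- tibble(repeat_id = "rep1", contig = loc$contig,
                             start = loc$start,
                             end = loc$start + nchar(hp_rep$precursor) - 1L,
                             strand = strand)
  }
  units$u_rep1 <- list(hp = hp_rep, arm_ratio = config$dominant_ratio)

  # --- planted structural ncRNA (source of screenable background)
  ncrna <- random_dna(2, 120)
  loc <- place_locus(120L)
  substr(contigs[[loc$contig]], loc$start, loc$start + 119L) <- ncrna[1]
  ncrna_locus <- tibble(contig = loc$contig, start = loc$start,
                        end = loc$start + 119L, strand = "+")

  genes <- bind_rows(genes)
  repeats <- bind_rows(rep_loci)

  # --- tissue profiles: expected reads per expression unit per sample
  samples <- sim_samples()
  unit_ids <- names(units)
  base <- setNames(exp(runif(length(unit_ids), log(300), log(1500))), unit_ids)
  base[startsWith(unit_ids, "u_novel")] <-
    exp(runif(sum(startsWith(unit_ids, "u_novel")), log(150), log(600)))
  base["u_rep1"] <- 350
  # biological variation is drawn per tissue (lognormal sd 0.25) and shared
  # by replicate libraries of that tissue; libraries add smaller technical
  # noise (sd 0.08), so replicate pairs correlate strongly as in real
  # small RNA profiling
  tissues <- unique(samples$tissue)
  tissue_w <- matrix(0, nrow = length(tissues), ncol = length(unit_ids),
                     dimnames = list(tissues, unit_ids))
  for (tis in tissues) {
    w <- base * exp(rnorm(length(base), 0, 0.25))
    w["u_mir736"] <- if (tis == "heart") 400 else 0
    w["u_mir212"] <- if (tis == "brain") 6000 else 30
    w["u_mir132"] <- if (tis == "brain") 2500 else 20
    w["u_novel1"] <- if (tis == "liver") 200 else 0
    tissue_w[tis, ] <- w
  }
  weights <- matrix(0, nrow = nrow(samples), ncol = length(unit_ids),
                    dimnames = list(samples$sample_id, unit_ids))
  for (i in seq_len(nrow(samples))) {
    weights[i, ] <- tissue_w[samples$tissue[i], ] *
      exp(rnorm(length(unit_ids), 0, 0.08))
    weights[i, tissue_w[samples$tissue[i], ] == 0] <- 0
  }
  gene_depth <- round(config$depth * (1 - config$background_rate))
  expected <- t(apply(weights, 1, function(w) gene_depth * w / sum(w)))
  tissue_profiles <- as_tibble(expected, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "unit_id",
                        values_to = "expected_reads") |>
    left_join(samples, by = "sample_id") |>
    select("sample_id", "tissue", "unit_id", "expected_reads")

  # --- hairpin reference: conserved precursors, mutated, + unrelated decoys
  ref <- character(0)
  for (fam in conserved_fams) {
    hp <- units[[paste0("u_mir", fam)]]$hp
    seq <- hp$precursor
    rate <- runif(1, 0, config$db_mut_rate)
    n_mut <- rbinom(1, nchar(seq), rate)
    if (n_mut > 0) {
      pos <- sample(seq_len(nchar(seq)), n_mut)
      for (p in pos) {
        cur <- substr(seq, p, p)
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    ref[paste0("dre-mir-", fam)] <- seq
  }
  for (k in seq_len(config$db_n_decoys)) {
    ref[paste0("dre-mir-", 9000 + k)] <- make_hairpin()$precursor
  }

  genome <- Biostrings::DNAStringSet(contigs)
  hairpin_db <- Biostrings::DNAStringSet(ref)
  screen_db <- Biostrings::DNAStringSet(setNames(ncrna, c("ncrna-1", "ncrna-2")))

  list(genome = genome,
       truth = list(genes = genes, repeats = repeats,
                    ncrna_locus = ncrna_locus,
                    tissue_profiles = tissue_profiles,
                    units = units, samples = samples),
       hairpin_db = hairpin_db, screen_db = screen_db)
}
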