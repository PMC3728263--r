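# End-to-end orchestration: simulate -> preprocess -> discover -> classify
# -> annotate -> quantify, with per-sample discovery and cross-sample
# merging of called precursor windows.

#' Pipeline configuration
#'
#' Collects paths (or in-memory objects) and all module parameters for
#' [run_discovery()]. Defaults follow the module-level defaults.
#'
#' @param genome Path to a genome FASTA or a named `DNAStringSet`.
#' @param manifest Path to a manifest TSV (`sample_id`, `tissue`, `fastq`)
#'   or a tibble.
#' @param hairpin_db Path to the hairpin reference FASTA or a
#'   `DNAStringSet`.
#' @param screen_db Optional ncRNA screen FASTA / `DNAStringSet`.
#' @param reference_clusters Optional reference cluster tibble or TSV path;
#'   defaults to the bundled [reference_clusters()].
#' @param out_dir Optional output directory for [report_tables()].
#' @param adaptor,min_len,max_len,min_quality Preprocessing parameters.
#' @param max_loci,min_stack_count,flank_long,flank_short Stack/excision
#'   parameters.
#' @param weights,n_shuffles,n_rounds,target_snr,calibration Scoring and
#'   calibration parameters; `calibration` is `"per_sample"` (each library
#'   calibrated independently) or `"global"`.
#' @param e_conserved,e_repeat,e_screen,max_repeat_hits Homology thresholds.
#' @param arm_fold,max_gap,prefix,novel_start Annotation parameters.
#' @param seed Seed for scoring/calibration randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, manifest, hairpin_db, screen_db = NULL,
                            reference_clusters = NULL, out_dir = NULL,
                            adaptor = "TGGAATTCTCGGGTGCCAAGG",
                            min_len = 18, max_len = 26, min_quality = 20,
                            max_loci = 50, min_stack_count = 2,
                            flank_long = 70, flank_short = 15,
                            weights = score_weights(), n_shuffles = 25,
                            n_rounds = 100, target_snr = 40,
                            calibration = c("per_sample", "global"),
                            e_conserved = 1e-7, e_repeat = 1e-6,
                            e_screen = 1e-6, max_repeat_hits = 5,
                            arm_fold = 2, max_gap = 10000, prefix = "ssa",
                            novel_start = 8000, seed = 1) {
  structure(list(genome = genome, manifest = manifest,
                 hairpin_db = hairpin_db, screen_db = screen_db,
                 reference_clusters = reference_clusters, out_dir = out_dir,
                 adaptor = adaptor, min_len = min_len, max_len = max_len,
                 min_quality = min_quality, max_loci = max_loci,
                 min_stack_count = min_stack_count, flank_long = flank_long,
                 flank_short = flank_short, weights = weights,
                 n_shuffles = n_shuffles, n_rounds = n_rounds,
                 target_snr = target_snr,
                 calibration = match.arg(calibration),
                 e_conserved = e_conserved, e_repeat = e_repeat,
                 e_screen = e_screen, max_repeat_hits = max_repeat_hits,
                 arm_fold = arm_fold, max_gap = max_gap, prefix = prefix,
                 novel_start = novel_start, seed = seed),
            class = "pipeline_config")
}

#' Simulate a full synthetic dataset to disk
#'
#' Wraps [build_toy_genome()] and [write_sample_libraries()]: writes the
#' genome, hairpin reference and ncRNA screen FASTAs, the per-sample FASTQ
#' libraries, the truth GFF3 and the sample manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return List with `paths` (named file paths), `manifest`, `truth`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- build_toy_genome(config)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                hairpin_db = file.path(out_dir, "hairpins.fa"),
                screen_db = file.path(out_dir, "screen.fa"),
                manifest = file.path(out_dir, "manifest.tsv"),
                truth = file.path(out_dir, "truth.gff3"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  Biostrings::writeXStringSet(sim$hairpin_db, paths$hairpin_db)
  Biostrings::writeXStringSet(sim$screen_db, paths$screen_db)
  manifest <- write_sample_libraries(sim$genome, sim$truth, config, out_dir)
  list(paths = paths, manifest = manifest, truth = sim$truth)
}

# resolve path-or-object inputs
load_fasta <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    Biostrings::DNAStringSet(x)
  } else {
    x
  }
}

load_manifest <- function(x) {
  if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else x
}

# Replace each candidate's founding-stack members with the complete read
# evidence inside its window (same contig and strand, alignment contained
# in the window), so that star reads on the opposite arm are visible.
attach_window_evidence <- function(candidates, alignments) {
  aln <- filter(alignments, !.data$flagged, .data$count > 0)
  out <- candidates
  for (i in seq_len(nrow(candidates))) {
    sel <- aln$contig == candidates$contig[i] &
      aln$strand == candidates$strand[i] &
      aln$start >= candidates$start[i] & aln$end <= candidates$end[i]
    out$members[[i]] <- select(aln[sel, ], "sequence", "start", "end", "count")
  }
  out
}

# Genomic coordinates of the reported precursor: the candidate window
# trimmed to the region covered by 5'-consistent mature-arm reads.
# Restricting to consistent reads keeps the trim independent of stray
# background fragments in the window, and taking exactly the read-covered
# span keeps it independent of locus-specific flanking sequence, so
# identical duplicated genes yield byte-identical trimmed precursors.
trim_precursor <- function(cand) {
  reads <- cand$members[[1]]
  ev <- partition_evidence(members_to_window(reads, cand),
                           cand$geometry[[1]])
  sel <- if (any(ev$consistent)) ev$consistent else rep(TRUE, nrow(reads))
  lo <- max(cand$start, min(reads$start[sel]))
  hi <- min(cand$end, max(reads$end[sel]))
  seq_w <- if (cand$strand == "+") {
    substr(cand$sequence, lo - cand$start + 1L, hi - cand$start + 1L)
  } else {
    substr(cand$sequence, cand$end - hi + 1L, cand$end - lo + 1L)
  }
  list(start = lo, end = hi, precursor = seq_w)
}

# per-sample discovery: stacks -> excision -> scoring -> calibration -> calls
discover_sample <- function(sample_id, unique_reads, alignments, index, cfg,
                            cache = NULL) {
  counts <- unique_reads[[sample_id]]
  aln <- mutate(alignments,
                count = counts[match(.data$sequence, unique_reads$sequence)])
  stacks <- find_stacks(aln, min_stack_count = cfg$min_stack_count)
  if (nrow(stacks) == 0) {
    return(list(sample_id = sample_id, scored = NULL, calibration = NULL,
                called = NULL))
  }
  cands <- excise_candidates(stacks, index, cfg$flank_long, cfg$flank_short)
  cands <- attach_window_evidence(cands, aln)
  scored <- score_candidates(cands, weights = cfg$weights,
                             n_shuffles = cfg$n_shuffles, cache = cache)
  scored$sample_id <- sample_id
  if (!any(is.finite(scored$total_score))) {
    return(list(sample_id = sample_id, scored = scored, calibration = NULL,
                called = NULL))
  }
  calibration <- NULL
  called <- NULL
  if (cfg$calibration == "per_sample") {
    calibration <- calibrate_cutoff(scored, n_rounds = cfg$n_rounds,
                                    target_snr = cfg$target_snr,
                                    weights = cfg$weights)
    called <- call_candidates(scored, calibration)
  }
  list(sample_id = sample_id, scored = scored, calibration = calibration,
       called = called)
}

# merge called windows across samples into locus groups by overlap
merge_called <- function(called) {
  gr <- GenomicRanges::GRanges(called$contig,
                               IRanges::IRanges(called$start, called$end),
                               strand = called$strand)
  red <- GenomicRanges::reduce(gr)
  called$locus_group <- GenomicRanges::findOverlaps(gr, red,
                                                    select = "first")
  called
}

#' Run the full discovery pipeline
#'
#' Per-sample discovery (read stacks, window excision, hairpin folding and
#' scoring, permutation-calibrated cutoff, candidate calls) followed by
#' cross-sample merging of called precursor loci, homology classification
#' (conserved family assignment, repeat and ncRNA screens, novel
#' validation), annotation (duplicates, nomenclature, arm dominance, gene
#' clusters and cluster groups, cluster conservation) and quantification
#' (count matrix, total-count normalization, replicate correlation,
#' tissue-presence scan, one-versus-rest differential expression per
#' tissue).
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `mirdisc_result`; see [report_tables()] for
#'   the serialized outputs.
#' @export
run_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  genome <- load_fasta(cfg$genome)
  manifest <- load_manifest(cfg$manifest)
  hairpin_db <- load_fasta(cfg$hairpin_db)
  screen_db <- if (is.null(cfg$screen_db)) NULL else load_fasta(cfg$screen_db)
  ref_clusters <- if (is.null(cfg$reference_clusters)) {
    reference_clusters()
  } else if (is.character(cfg$reference_clusters)) {
    readr::read_tsv(cfg$reference_clusters, show_col_types = FALSE)
  } else {
    cfg$reference_clusters
  }

  pre <- preprocess_libraries(manifest, adaptor = cfg$adaptor,
                              min_len = cfg$min_len, max_len = cfg$max_len,
                              min_quality = cfg$min_quality)
  unique_reads <- pre$unique_reads
  index <- build_index(genome)
  alignments <- map_reads(unique_reads, index, max_loci = cfg$max_loci)

  memo <- new.env(parent = emptyenv())
  per_sample <- purrr::map(manifest$sample_id, function(sid) {
    discover_sample(sid, unique_reads, alignments, index, cfg, cache = memo)
  })
  names(per_sample) <- manifest$sample_id

  all_scored <- bind_rows(purrr::map(per_sample, "scored"))
  calibrations <- purrr::map(per_sample, "calibration")
  if (cfg$calibration == "global") {
    stopifnot(any(is.finite(all_scored$total_score)))
    glob <- calibrate_cutoff(all_scored, n_rounds = cfg$n_rounds,
                             target_snr = cfg$target_snr,
                             weights = cfg$weights)
    calibrations <- list(global = glob)
    called <- call_candidates(all_scored, glob)
  } else {
    called <- bind_rows(purrr::map(per_sample, "called"))
  }
  if (is.null(called) || nrow(called) == 0) {
    stop("discovery produced no called candidates", call. = FALSE)
  }
  called <- merge_called(called)

  # representative window per merged locus: highest-scoring call
  reps <- called |>
    group_by(.data$locus_group) |>
    dplyr::slice_max(.data$total_score, n = 1, with_ties = FALSE) |>
    ungroup()
  detected_in <- called |>
    group_by(.data$locus_group) |>
    summarise(samples_called = list(sort(unique(.data$sample_id))),
              .groups = "drop")
  reps <- left_join(reps, detected_in, by = "locus_group")

  # merged evidence across samples for validation statistics
  totals <- unique_reads$total
  aln_total <- mutate(alignments,
                      count = totals[match(.data$sequence,
                                           unique_reads$sequence)])
  reps <- attach_window_evidence(reps, aln_total)

  trims <- purrr::map(seq_len(nrow(reps)), function(i) trim_precursor(reps[i, ]))
  reps$precursor <- purrr::map_chr(trims, "precursor")
  reps$prec_start <- purrr::map_int(trims, function(x) as.integer(x$start))
  reps$prec_end <- purrr::map_int(trims, function(x) as.integer(x$end))

  # ---- homology track -------------------------------------------------
  params <- karlin_params()
  cls <- classify_conserved(
    tibble(candidate_id = reps$candidate_id, sequence = reps$precursor),
    hairpin_db, e_threshold = cfg$e_conserved, params = params)
  reps <- bind_cols(reps, select(cls, -"candidate_id"))

  rep_scr <- purrr::map(reps$precursor, function(s) {
    repeat_screen(s, index, e_threshold = cfg$e_repeat,
                  max_hits = cfg$max_repeat_hits, params = params)
  })
  reps$locus_count <- purrr::map_int(rep_scr, function(x) as.integer(x$locus_count))
  reps$repeat_keep <- purrr::map_lgl(rep_scr, "keep")

  nc_scr <- purrr::map(seq_len(nrow(reps)), function(i) {
    ncrna_screen(reps$precursor[i],
                 matures = c(reps$mature5p[i], reps$mature3p[i]),
                 screen_db = screen_db, e_threshold = cfg$e_screen,
                 params = params)
  })
  reps$screen_keep <- purrr::map_lgl(nc_scr, "keep")

  # per-sample detection by perfect mature matches
  sample_ids <- manifest$sample_id
  detect_n <- purrr::map_int(seq_len(nrow(reps)), function(i) {
    mats <- stats::na.omit(c(reps$mature5p[i], reps$mature3p[i]))
    hit <- unique_reads$sequence %in% mats
    if (!any(hit)) return(0L)
    sum(vapply(sample_ids,
               function(s) sum(unique_reads[[s]][hit]) > 0, logical(1)))
  })
  reps$n_samples_detected <- detect_n

  # 5' processing consistency from merged evidence
  fpc <- purrr::map_dbl(seq_len(nrow(reps)), function(i) {
    cand <- reps[i, ]
    geom <- cand$geometry[[1]]
    reads <- members_to_window(cand$members[[1]], cand)
    ev <- partition_evidence(reads, geom, tol = 0L)
    ev$f_consistent
  })
  reps$five_prime_consistency <- fpc

  nov <- validate_novel(reps$n_samples_detected,
                        has_5p_reads = reps$n5p > 0,
                        has_3p_reads = reps$n3p > 0,
                        five_prime_consistency = reps$five_prime_consistency,
                        genome_locus_count = reps$locus_count,
                        screens_passed = reps$repeat_keep & reps$screen_keep)
  reps$novel_verdict <- nov$verdict

  reps$status <- dplyr::case_when(
    !reps$repeat_keep ~ "repeat_excluded",
    !reps$screen_keep ~ "screen_excluded",
    !is.na(reps$family) ~ "conserved",
    reps$novel_verdict ~ "novel",
    TRUE ~ "novel_unvalidated"
  )

  # ---- annotation track ----------------------------------------------
  kept <- filter(reps, .data$status %in% c("conserved", "novel"))
  if (nrow(kept) == 0) stop("no genes survived the screens", call. = FALSE)
  loci <- tibble(contig = kept$contig, start = kept$prec_start,
                 end = kept$prec_end, strand = kept$strand,
                 precursor = kept$precursor, mature5p = kept$mature5p,
                 mature3p = kept$mature3p, family = kept$family,
                 origin = ifelse(kept$status == "conserved", "conserved",
                                 "novel"),
                 locus_group = kept$locus_group)
  loci <- resolve_duplicates(loci)
  loci <- assign_names(loci, prefix = cfg$prefix,
                       novel_start = cfg$novel_start)

  genes <- purrr::map(split(seq_len(nrow(loci)), loci$name), function(ix) {
    m <- loci[ix, ]
    tibble(name = m$name[1], family = m$family[1], origin = m$origin[1],
           precursor = m$precursor[1], mature5p = m$mature5p[1],
           mature3p = m$mature3p[1], n_loci = nrow(m),
           loci = list(m[, c("contig", "start", "end", "strand")]))
  }) |> bind_rows()

  arms <- arm_read_counts(genes, unique_reads)
  genes <- left_join(genes, arms, by = c(name = "mirna")) |>
    mutate(dominant_arm = call_arm_dominance(.data$count5p, .data$count3p,
                                             fold = cfg$arm_fold))

  clusters <- detect_clusters(select(loci, "name", "family", "contig",
                                     "start", "end", "strand"),
                              max_gap = cfg$max_gap)
  groups <- group_clusters(clusters)
  conservation <- compare_cluster_conservation(groups, ref_clusters)

  # ---- expression track ----------------------------------------------
  counts <- build_count_matrix(genes, unique_reads)
  norm <- normalize_counts(counts)
  presence <- tissue_presence_scan(counts, manifest)
  de <- purrr::map(sort(unique(manifest$tissue)), function(tis) {
    if (sum(manifest$tissue == tis) == nrow(manifest)) return(NULL)
    one_vs_rest_test(counts, manifest, tis)
  }) |> bind_rows()

  dup_tissue <- manifest |> count(.data$tissue) |> filter(.data$n >= 2)
  rep_cor <- NA_real_
  if (nrow(dup_tissue) > 0) {
    pair <- manifest$sample_id[manifest$tissue == dup_tissue$tissue[1]][1:2]
    rep_cor <- tryCatch(
      replicate_correlation(norm$normalized, pair[1], pair[2]),
      error = function(e) NA_real_)
  }

  gene_table <- genes |>
    mutate(tissues = purrr::map_chr(.data$name, function(nm) {
      tt <- presence$tissues[[match(nm, presence$mirna)]]
      if (length(tt) == 0) "none"
      else if (length(tt) == 1) tt
      else "multiple"
    })) |>
    select("name", "mature5p", "mature3p", "precursor", "n_loci", "tissues",
           "dominant_arm", "origin", "family", "count5p", "count3p")

  result <- structure(list(
    genes = genes, gene_table = gene_table, loci = loci,
    clusters = clusters, cluster_groups = groups,
    conservation = conservation, counts = counts,
    normalized = norm$normalized, size_factors = norm$size_factors,
    de = de, presence = presence, replicate_r = rep_cor,
    calibrations = calibrations, candidates = reps,
    summaries = pre$summaries, manifest = manifest, config = cfg
  ), class = "mirdisc_result")
  if (!is.null(cfg$out_dir)) report_tables(result, cfg$out_dir)
  result
}

#' @export
print.mirdisc_result <- function(x, ...) {
  cat("<mirdisc_result>\n")
  cat("  genes:", nrow(x$genes),
      sprintf("(%d conserved, %d novel)",
              sum(x$genes$origin == "conserved"),
              sum(x$genes$origin == "novel")), "\n")
  cat("  loci:", nrow(x$loci), " clusters:", nrow(x$clusters),
      " cluster groups:",
      sum(!is.na(x$cluster_groups$group_id)), "\n")
  cat("  samples:", nrow(x$manifest), " replicate r:",
      format(x$replicate_r, digits = 3), "\n")
  invisible(x)
}

#' Write the result bundle as TSV/GFF3 report tables
#'
#' Gene table (name, matures, precursor, locus count, tissues, dominant
#' arm), cluster and cluster-group tables, cluster conservation table, raw
#' and normalized count matrices, differential expression results,
#' calibration tables, sample summaries and a GFF3 of gene loci.
#'
#' @param result A `mirdisc_result`.
#' @param out_dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
report_tables <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    gene_table = file.path(out_dir, "gene_table.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    cluster_groups = file.path(out_dir, "cluster_groups.tsv"),
    conservation = file.path(out_dir, "cluster_conservation.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    normalized = file.path(out_dir, "normalized_counts.tsv"),
    de = file.path(out_dir, "de_results.tsv"),
    summaries = file.path(out_dir, "sample_summaries.tsv"),
    calibration = file.path(out_dir, "calibration.tsv"),
    candidates = file.path(out_dir, "candidate_report.tsv"),
    gff = file.path(out_dir, "genes.gff3"),
    run_log = file.path(out_dir, "run_log.txt")
  )
  readr::write_tsv(result$gene_table, p$gene_table)
  cl <- result$clusters |>
    mutate(members = purrr::map_chr(.data$members,
                                    function(m) paste(m$name, collapse = ",")),
           gaps = purrr::map_chr(.data$gaps,
                                 function(g) paste(g, collapse = ",")))
  readr::write_tsv(cl, p$clusters)
  gg <- result$cluster_groups |>
    mutate(cluster_ids = purrr::map_chr(.data$cluster_ids, paste,
                                        collapse = ","),
           contigs = purrr::map_chr(.data$contigs, paste, collapse = ","))
  readr::write_tsv(gg, p$cluster_groups)
  cons <- result$conservation |>
    mutate(cluster_ids = purrr::map_chr(.data$cluster_ids, paste,
                                        collapse = ","),
           contigs = purrr::map_chr(.data$contigs, paste, collapse = ","))
  readr::write_tsv(cons, p$conservation)
  readr::write_tsv(result$counts, p$counts)
  readr::write_tsv(result$normalized, p$normalized)
  readr::write_tsv(result$de, p$de)
  readr::write_tsv(result$summaries, p$summaries)
  calib <- purrr::imap(result$calibrations, function(cc, sid) {
    if (is.null(cc)) return(NULL)
    mutate(cc$table, sample_id = sid, chosen_cutoff = cc$cutoff)
  }) |> bind_rows()
  readr::write_tsv(calib, p$calibration)
  cand_cols <- intersect(
    c("candidate_id", "contig", "start", "end", "strand", "sample_id",
      "fold_score", "z_struct", "f_consistent", "n_consistent", "star",
      "n5p", "n3p", "n_loop", "n_inconsistent", "total_score", "mature5p",
      "mature3p", "precursor", "family", "best_hit", "hit_evalue",
      "hit_identity", "locus_count", "n_samples_detected",
      "five_prime_consistency", "status"),
    names(result$candidates))
  readr::write_tsv(result$candidates[, cand_cols], p$candidates)
  cfg <- result$config
  writeLines(c(
    paste("mirdisc", as.character(utils::packageVersion("mirdisc"))),
    R.version.string,
    paste("seed:", cfg$seed),
    paste("calibration:", cfg$calibration, "| rounds:", cfg$n_rounds,
          "| target SNR:", cfg$target_snr),
    paste("adaptor:", cfg$adaptor, "| size filter:", cfg$min_len, "-",
          cfg$max_len, "| min quality:", cfg$min_quality),
    paste("E thresholds: conserved", cfg$e_conserved, "| repeat",
          cfg$e_repeat, "| screen", cfg$e_screen,
          "| max repeat loci:", cfg$max_repeat_hits),
    paste("cluster gap:", cfg$max_gap, "| arm fold:", cfg$arm_fold)
  ), p$run_log)
  gr_rows <- result$loci
  gr <- GenomicRanges::GRanges(gr_rows$contig,
                               IRanges::IRanges(gr_rows$start, gr_rows$end),
                               strand = gr_rows$strand,
                               type = "miRNA_primary_transcript",
                               Name = gr_rows$name,
                               copy_group = gr_rows$copy_group)
  rtracklayer::export(gr, p$gff, format = "gff3")
  invisible(p)
}

#' Evaluate a discovery result against the simulation truth
#'
#' Matches reported gene loci to planted loci by same-strand overlap.
#'
#' @param result A `mirdisc_result`.
#' @param truth Truth list from [build_toy_genome()].
#' @return List with `recall`, `precision`, `label_agreement` (conserved /
#'   novel labels on matched loci), `decoys_excluded` (fraction of planted
#'   repeat loci absent from the gene table) and the matching tables.
#' @export
evaluate_discovery <- function(result, truth) {
  found <- result$loci
  fg <- GenomicRanges::GRanges(found$contig,
                               IRanges::IRanges(found$start, found$end),
                               strand = found$strand)
  tg <- GenomicRanges::GRanges(truth$genes$contig,
                               IRanges::IRanges(truth$genes$start,
                                                truth$genes$end),
                               strand = truth$genes$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(tg, fg))
  recovered <- unique(S4Vectors::queryHits(hits))
  matched_found <- unique(S4Vectors::subjectHits(hits))
  recall <- length(recovered) / length(tg)
  precision <- length(matched_found) / length(fg)
  # conserved/novel label agreement on matched truth loci
  lab <- purrr::map_lgl(seq_along(tg), function(i) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(j) == 0) return(NA)
    any((found$origin[j] == "conserved") ==
          truth$genes$is_conserved_homolog[i])
  })
  label_agreement <- mean(lab, na.rm = TRUE)
  rg <- GenomicRanges::GRanges(truth$repeats$contig,
                               IRanges::IRanges(truth$repeats$start,
                                                truth$repeats$end),
                               strand = truth$repeats$strand)
  decoy_hits <- suppressWarnings(GenomicRanges::countOverlaps(rg, fg))
  decoys_excluded <- mean(decoy_hits == 0)
  list(recall = recall, precision = precision,
       label_agreement = label_agreement,
       decoys_excluded = decoys_excluded,
       n_truth = length(tg), n_found = length(fg),
       missed = truth$genes[setdiff(seq_along(tg), recovered), ])
}
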