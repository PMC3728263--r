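small_sim_config <- function(seed = 301) {
  sim_config(genome_size = 400000, n_contigs = 16, depth = 4000, seed = seed)
}

test_that("the toy genome is reproducible and respects its invariants", {
  cfg <- small_sim_config()
  a <- build_toy_genome(cfg)
  b <- build_toy_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$genes, b$truth$genes)
  g <- a$truth$genes
  # coordinates inside contigs, precursors 60-80 nt, matures on precursor
  widths <- Biostrings::width(a$genome)
  names(widths) <- names(a$genome)
  expect_true(all(g$start >= 1 & g$end <= widths[g$contig]))
  len <- g$end - g$start + 1
  expect_true(all(len >= 60 & len <= 80))
  expect_true(all(mapply(grepl, g$mature5p, g$precursor, fixed = TRUE)))
  expect_true(all(mapply(grepl, g$mature3p, g$precursor, fixed = TRUE)))
  # planted genome spells the precursor at each locus
  for (i in seq_len(nrow(g))) {
    sub <- substr(as.character(a$genome[[g$contig[i]]]), g$start[i], g$end[i])
    if (g$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_identical(sub, g$precursor[i])
  }
  # each copy group shares an identical precursor at distinct loci
  cg <- g[!is.na(g$copy_group), ]
  for (grp in split(cg, cg$copy_group)) {
    expect_gte(nrow(grp), 2)
    expect_equal(length(unique(grp$precursor)), 1)
    expect_gt(length(unique(paste(grp$contig, grp$start))), 1)
  }
  # every cluster id groups >= 2 same-strand genes < 10 kb apart
  cl <- g[!is.na(g$cluster_id), ]
  for (grp in split(cl, cl$cluster_id)) {
    expect_gte(nrow(grp), 2)
    expect_equal(length(unique(grp$strand)), 1)
    expect_equal(length(unique(grp$contig)), 1)
    expect_lt(min(grp$start[-1]) - max(grp$end[-nrow(grp)]), 10000)
  }
})

test_that("the repeat decoy is planted at exactly repeat_copy_number loci", {
  cfg <- small_sim_config(seed = 311)
  sim <- build_toy_genome(cfg)
  rep_seq <- NULL
  r <- sim$truth$repeats
  expect_equal(nrow(r), cfg$repeat_copy_number)
  gseq <- as.character(sim$genome)
  first <- substr(gseq[[r$contig[1]]], r$start[1], r$end[1])
  if (r$strand[1] == "-") {
    first <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(first)))
  }
  # brute-force substring count over both strands of the emitted genome
  n_found <- 0
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(first)))
  for (ctg in gseq) {
    for (target in unique(c(first, rc))) {
      m <- gregexpr(target, ctg, fixed = TRUE)[[1]]
      n_found <- n_found + sum(m > 0)
    }
  }
  expect_equal(n_found, cfg$repeat_copy_number)
})

test_that("the hairpin reference contains conserved genes and no novel genes", {
  sim <- build_toy_genome(small_sim_config(seed = 321))
  db <- as.character(sim$hairpin_db)
  g <- sim$truth$genes
  conserved <- g[g$is_conserved_homolog, ]
  for (fam in unique(conserved$family)) {
    expect_true(any(names(db) == paste0("dre-mir-", fam)))
  }
  novel_prec <- unique(g$precursor[!g$is_conserved_homolog])
  expect_false(any(novel_prec %in% db))
})

test_that("Dicer read simulation honours arm ratio and jitter", {
  set.seed(331)
  hp <- mirdisc:::make_hairpin()
  expect_equal(simulate_dicer_reads(hp, 0, 20), character(0))
  # degenerate jitter: every mature read shares its arm's modal 5' start
  set.seed(333)
  reads <- simulate_dicer_reads(hp, 600, 20, jitter = c(1, 0, 0),
                                loop_fraction = 0)
  m5 <- substr(hp$precursor, hp$m5_start, hp$m5_start + 17)
  m3 <- substr(hp$precursor, hp$m3_start, hp$m3_start + 17)
  is5 <- startsWith(reads, substr(m5, 1, 12))
  is3 <- startsWith(reads, substr(m3, 1, 12))
  expect_equal(sum(is5) + sum(is3), 600)
  # 20:1 arm ratio: 5p share close to 20/21
  set.seed(335)
  reads2 <- simulate_dicer_reads(hp, 2100, 20, jitter = c(1, 0, 0),
                                 loop_fraction = 0)
  share <- mean(startsWith(reads2, substr(m5, 1, 12)))
  expect_lt(abs(share - 20 / 21), 3 * sqrt((20 / 21) * (1 / 21) / 2100) + 1e-9)
  # read lengths stay in the mature window
  expect_true(all(nchar(reads2) >= 18 & nchar(reads2) <= 26))
  # determinism
  set.seed(9); r1 <- simulate_dicer_reads(hp, 200, 20)
  set.seed(9); r2 <- simulate_dicer_reads(hp, 200, 20)
  expect_identical(r1, r2)
})

test_that("the empirical 5p fraction converges to its expectation", {
  set.seed(341)
  hp <- mirdisc:::make_hairpin()
  m5 <- substr(hp$precursor, hp$m5_start, hp$m5_start + 11)
  for (ar in c(0.25, 1, 4)) {
    reads <- simulate_dicer_reads(hp, 20000, ar, jitter = c(1, 0, 0),
                                  loop_fraction = 0)
    share <- mean(startsWith(reads, m5))
    expect_equal(share, ar / (1 + ar), tolerance = 0.03)
  }
})

test_that("libraries carry adaptor read-through and honour truth profiles", {
  cfg <- small_sim_config(seed = 351)
  sim <- build_toy_genome(cfg)
  out <- withr::local_tempdir()
  manifest <- write_sample_libraries(sim$genome, sim$truth, cfg, out)
  expect_equal(nrow(manifest), 12)
  expect_true(all(file.exists(manifest$fastq)))
  expect_true(file.exists(file.path(out, "truth.gff3")))
  # a 22-nt insert plus the 21-nt adaptor truncated to 32 keeps 10 adaptor nt
  insert22 <- paste0(strrep("A", 22))
  raw <- substr(paste0(insert22, cfg$adaptor), 1, cfg$read_length)
  expect_equal(nchar(raw), 32)
  expect_equal(substr(raw, 23, 32), substr(cfg$adaptor, 1, 10))
  # every emitted read is exactly the configured read length
  fq <- readLines(manifest$fastq[1])
  seqs <- fq[seq(2, length(fq), by = 4)]
  expect_true(all(nchar(seqs) == cfg$read_length))
  # the liver-restricted gene leaves no reads in non-liver libraries
  g <- sim$truth$genes
  liv_unit <- "u_novel1"
  liv_gene <- g[g$unit_id == liv_unit, ][1, ]
  profiles <- sim$truth$tissue_profiles
  expect_true(all(profiles$expected_reads[profiles$unit_id == liv_unit &
                                            profiles$tissue != "liver"] == 0))
  probe <- substr(liv_gene$mature5p, 3, 18)
  for (i in which(manifest$tissue != "liver")) {
    fq_i <- readLines(manifest$fastq[i])
    seqs_i <- fq_i[seq(2, length(fq_i), by = 4)]
    expect_false(any(grepl(probe, seqs_i, fixed = TRUE)),
                 info = manifest$sample_id[i])
  }
  # determinism of the full library set
  out2 <- withr::local_tempdir()
  write_sample_libraries(sim$genome, sim$truth, cfg, out2)
  expect_identical(readLines(manifest$fastq[1]),
                   readLines(file.path(out2, basename(manifest$fastq[1]))))
})

test_that("zero background rate leaves only gene-derived reads", {
  cfg <- sim_config(genome_size = 400000, n_contigs = 16, depth = 800,
                    background_rate = 0, seed = 361)
  sim <- build_toy_genome(cfg)
  out <- withr::local_tempdir()
  manifest <- write_sample_libraries(sim$genome, sim$truth, cfg, out)
  fq <- readLines(manifest$fastq[3])
  seqs <- fq[seq(2, length(fq), by = 4)]
  inserts <- trim_adaptor(seqs, cfg$adaptor)
  sources <- c(vapply(sim$truth$units, function(u) u$hp$precursor,
                      character(1)))
  traced <- vapply(inserts, function(x) {
    nchar(x) < 15 || any(vapply(sources, function(s) {
      grepl(x, s, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  expect_true(all(traced))
})
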