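make_toy_index <- function(seed = 17, n = 2, len = 4000) {
  set.seed(seed)
  g <- setNames(vapply(seq_len(n), function(i) random_seq(len), character(1)),
                paste0("c", seq_len(n)))
  build_index(g)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

test_that("exact mapping equals brute-force substring search on both strands", {
  idx <- make_toy_index()
  gseqs <- as.character(idx$genome)
  set.seed(23)
  queries <- c(
    vapply(1:15, function(i) {           # planted plus-strand reads
      ctg <- sample(names(gseqs), 1)
      st <- sample(3000, 1)
      substr(gseqs[[ctg]], st, st + sample(18:26, 1) - 1)
    }, character(1)),
    vapply(1:15, function(i) {           # planted minus-strand reads
      ctg <- sample(names(gseqs), 1)
      st <- sample(3000, 1)
      revcomp_chr(substr(gseqs[[ctg]], st, st + sample(18:26, 1) - 1))
    }, character(1))
  )
  aln <- map_reads(queries, idx)
  for (q in queries) {
    hits <- aln[aln$sequence == q, ]
    n_brute <- 0
    for (ctg in names(gseqs)) {
      for (target in c(q, revcomp_chr(q))) {
        m <- gregexpr(target, gseqs[[ctg]], fixed = TRUE)[[1]]
        n_brute <- n_brute + sum(m > 0)
      }
    }
    expect_equal(nrow(hits), n_brute, info = q)
    # reported loci spell the read (reverse-complemented on minus)
    for (r in seq_len(nrow(hits))) {
      sub <- substr(gseqs[[hits$contig[r]]], hits$start[r], hits$end[r])
      if (hits$strand[r] == "-") sub <- revcomp_chr(sub)
      expect_identical(sub, q)
    }
  }
  # a random 26-mer absent from the toy genome maps nowhere
  set.seed(99)
  absent <- "TTTTTTTTTTGGGGGGGGGGCCCCCC"
  expect_equal(nrow(map_reads(absent, idx)), 0)
})

test_that("multi-locus reads are counted and flagged beyond max_loci", {
  set.seed(31)
  core <- random_seq(24)
  g <- paste0(random_seq(100), core, random_seq(100), core,
              random_seq(100), core, random_seq(100))
  idx <- build_index(c(chrA = g))
  aln <- map_reads(core, idx)
  expect_equal(unique(aln$n_loci), 3L)
  expect_false(any(aln$flagged))
  aln2 <- map_reads(core, idx, max_loci = 2)
  expect_true(all(aln2$flagged))
  # flagged reads are excluded from stacks
  aln2$count <- 5
  expect_equal(nrow(find_stacks(aln2)), 0)
})

test_that("stack chaining merges overlapping reads and splits distant ones", {
  aln <- tibble::tibble(
    sequence = c("r1", "r2", "r3"),
    contig = "c1", strand = "+",
    start = c(100L, 110L, 300L), end = c(121L, 131L, 321L),
    n_loci = 1L, flagged = FALSE, count = c(3, 2, 7)
  )
  st <- find_stacks(aln)
  expect_equal(nrow(st), 2)
  expect_equal(st$total_count, c(5, 7))
  expect_equal(st$start[1], 100L)
  expect_equal(st$end[1], 131L)
  # modal 5' end is the highest-count start
  expect_equal(st$modal5p[1], 100L)
  # below the stack-count floor: dropped
  aln$count <- c(1, 0, 1)
  expect_equal(nrow(find_stacks(aln)), 0)
  aln$count <- c(1, 1, 1)
  expect_equal(nrow(find_stacks(aln)), 1)
})

test_that("stacks partition the unflagged alignments", {
  idx <- make_toy_index(seed = 53)
  gseqs <- as.character(idx$genome)
  set.seed(53)
  reads <- vapply(1:60, function(i) {
    ctg <- sample(names(gseqs), 1)
    st <- sample(3500, 1)
    substr(gseqs[[ctg]], st, st + 21)
  }, character(1))
  aln <- map_reads(reads, idx)
  aln$count <- 2
  st <- find_stacks(aln)
  n_members <- sum(vapply(st$members, nrow, integer(1)))
  expect_equal(n_members, nrow(aln))
})

test_that("excision yields clipped, strand-correct windows", {
  idx <- make_toy_index(seed = 61)
  gseqs <- as.character(idx$genome)
  stacks <- tibble::tibble(
    stack_id = c("s1", "s2", "s3"),
    contig = "c1", strand = c("+", "+", "-"),
    start = c(1000L, 3L, 2000L), end = c(1021L, 24L, 2021L),
    total_count = 10, modal5p = c(1000L, 3L, 2021L),
    members = list(tibble::tibble(sequence = "x", start = 1000L,
                                  end = 1021L, count = 10),
                   tibble::tibble(sequence = "x", start = 3L,
                                  end = 24L, count = 10),
                   tibble::tibble(sequence = "x", start = 2000L,
                                  end = 2021L, count = 10))
  )
  cands <- excise_candidates(stacks, idx)
  c1 <- cands[cands$stack_id == "s1", ]
  expect_equal(nrow(c1), 2)                       # 5p and 3p hypotheses
  expect_equal(nchar(c1$sequence), c1$end - c1$start + 1L)
  expect_equal(sort(nchar(c1$sequence)), c(107L, 107L))
  # window sequence contains the stack span at the mature offset
  for (r in seq_len(nrow(cands))) {
    w <- cands[r, ]
    mat <- substr(w$sequence, w$mature_start, w$mature_end)
    gsub <- substr(gseqs[[w$contig]],
                   if (w$strand == "+") w$start + w$mature_start - 1L
                   else w$end - w$mature_end + 1L,
                   if (w$strand == "+") w$start + w$mature_end - 1L
                   else w$end - w$mature_start + 1L)
    if (w$strand == "-") gsub <- revcomp_chr(gsub)
    expect_identical(mat, gsub)
  }
  # stack near the contig start is clipped, not an error
  c2 <- cands[cands$stack_id == "s2", ]
  expect_true(all(c2$start >= 1))
  expect_true(all(nchar(c2$sequence) < 107))
})
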