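test_that("local alignment handles identity, noise and input errors", {
  q <- random_seq(20)
  a <- smith_waterman(q, q)
  expect_equal(a$score, 20)
  expect_equal(a$identity, 100)
  expect_equal(c(a$qstart, a$qend), c(1, 20))
  # unrelated sequences yield only short chance alignments
  set.seed(3)
  b <- smith_waterman(random_seq(30),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(random_seq(30)))))
  expect_lt(b$score, 8)
  expect_error(smith_waterman("", "ACGT"), "non-empty")
})

test_that("local alignment equals a recursive brute-force oracle", {
  set.seed(19)
  for (k in 1:30) {
    q <- random_seq(sample(5:8, 1))
    s <- random_seq(sample(5:8, 1))
    expect_equal(smith_waterman(q, s)$score, oracle_local_align(q, s),
                 info = paste(q, s))
  }
  # with gaps worth opening
  q <- "ACGTACGTAC"
  s <- "ACGTTTACGTAC"
  expect_equal(smith_waterman(q, s)$score, oracle_local_align(q, s))
})

test_that("Karlin-Altschul parameters and E-values behave as required", {
  kp <- karlin_params()
  # independent bisection root of 0.25 e^l + 0.75 e^-2l = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 0.5; hi <- 3
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(kp$lambda, (lo + hi) / 2, tolerance = 1e-8)
  # analytic root: log((3 + sqrt(21)) / 2)
  expect_equal(kp$lambda, log((3 + sqrt(21)) / 2), tolerance = 1e-9)
  # doubling the database doubles E at fixed score
  expect_equal(evalue(30, 70, 2e5), 2 * evalue(30, 70, 1e5))
  # E is monotone decreasing in the score and vanishes in the limit
  expect_true(all(diff(evalue(seq(10, 60, 5), 70, 1e5)) < 0))
  expect_lt(evalue(1e4, 70, 1e5), 1e-300)
  expect_error(evalue(10, 0, 100), "positive")
})

test_that("conserved classification assigns the best family at the threshold", {
  set.seed(47)
  prec <- random_seq(65)
  mutated <- prec
  for (p in sample(65, 4)) {                 # ~6% divergence
    cur <- substr(mutated, p, p)
    substr(mutated, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  db <- c("dre-mir-199" = mutated,
          "dre-mir-205" = random_seq(65),
          "dre-let-7a" = random_seq(70))
  cand <- tibble::tibble(candidate_id = c("a", "b"),
                         sequence = c(prec, random_seq(65)))
  cls <- classify_conserved(cand, db)
  expect_equal(cls$family[1], "199")
  expect_lte(cls$hit_evalue[1], 1e-7)
  expect_true(is.na(cls$family[2]))          # unrelated: novel track
  # threshold is inclusive: exactly E -> conserved
  cls_b <- classify_conserved(cand[2, ], db,
                              e_threshold = cls$hit_evalue[2])
  expect_false(is.na(cls_b$family))
  expect_warning(out <- classify_conserved(cand, character(0)), "empty")
  expect_true(all(is.na(out$family)))
})

test_that("repeat screen counts loci and applies the >5 rule", {
  set.seed(59)
  unit <- random_seq(60)
  spacer <- function() random_seq(400)
  make_genome <- function(copies) {
    g <- spacer()
    for (i in seq_len(copies)) g <- paste0(g, unit, spacer())
    build_index(c(chr1 = g))
  }
  r5 <- repeat_screen(unit, make_genome(5))
  expect_equal(r5$locus_count, 5)
  expect_true(r5$keep)                        # exactly 5 loci: kept
  r6 <- repeat_screen(unit, make_genome(6))
  expect_equal(r6$locus_count, 6)
  expect_false(r6$keep)                       # >5 loci: excluded
  single <- repeat_screen(unit, make_genome(1))
  expect_equal(single$locus_count, 1)         # the self hit
  expect_true(single$keep)
})

test_that("ncRNA screen excludes database hits and keeps the rest", {
  set.seed(67)
  nc <- random_seq(120)
  db <- c("ncrna-1" = nc)
  frag <- substr(nc, 20, 85)
  expect_false(ncrna_screen(frag, screen_db = db)$keep)
  expect_true(ncrna_screen(random_seq(66), screen_db = db)$keep)
  expect_true(ncrna_screen(frag, screen_db = NULL)$keep)
})

test_that("novel validation applies the full cascade", {
  pass <- validate_novel(2, TRUE, TRUE, 0.9)
  expect_true(pass$verdict)
  expect_false(validate_novel(1, TRUE, TRUE, 0.9)$verdict)   # one sample only
  expect_false(validate_novel(3, TRUE, FALSE, 0.9)$verdict)  # no star arm read
  expect_false(validate_novel(3, TRUE, TRUE, 0.5)$verdict)   # consistency not > 0.5
  expect_false(validate_novel(3, TRUE, TRUE, 0.9,
                              screens_passed = FALSE)$verdict)
})
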