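toy_counts <- function() {
  tibble::tibble(
    mirna = c("m1", "m2", "m3", "m4"),
    s1 = c(100, 50, 10, 0),
    s2 = c(200, 100, 20, 0),
    s3 = c(50, 200, 5, 3),
    s4 = c(60, 180, 8, 2)
  )
}

test_that("the count matrix counts perfect mature matches per sample", {
  genes <- tibble::tibble(
    name = c("gA", "gB"),
    mature5p = c("ACGTACGTACGTACGTACGTA", "TTTTACGTACGTACGTACGTA"),
    mature3p = c("CCGTACGTACGTACGTACGTA", "GGGGACGTACGTACGTACGTA")
  )
  ur <- collapse_reads(list(
    s1 = c(rep(genes$mature5p[1], 5), genes$mature3p[1], "AAAAAAAAAAAAAAAAAAA"),
    s2 = c(genes$mature5p[1], rep(genes$mature5p[2], 3))
  ))
  cm <- build_count_matrix(genes, ur)
  expect_equal(cm$s1[cm$mirna == "gA"], 6)   # 5 x 5p + 1 x 3p
  expect_equal(cm$s2[cm$mirna == "gA"], 1)
  expect_equal(cm$s1[cm$mirna == "gB"], 0)   # absent gene
  expect_equal(cm$s2[cm$mirna == "gB"], 3)
})

test_that("total-count normalization is scale invariant", {
  cm <- toy_counts()
  norm <- normalize_counts(cm)
  # two columns with identical totals keep their values
  cm2 <- cm
  cm2$s2 <- cm2$s1
  n2 <- normalize_counts(cm2)
  expect_equal(n2$normalized$s1, n2$normalized$s2)
  # doubling a column's raw counts leaves normalized values unchanged
  # (up to the shared reference rescale, which cancels in ratios)
  cm3 <- cm
  cm3$s1 <- cm3$s1 * 2
  n3 <- normalize_counts(cm3)
  r1 <- norm$normalized$s1 / sum(norm$normalized$s1)
  r3 <- n3$normalized$s1 / sum(n3$normalized$s1)
  expect_equal(r1, r3)
  expect_equal(unname(norm$size_factors),
               unname(colSums(as.matrix(cm[, -1])) /
                        exp(mean(log(colSums(as.matrix(cm[, -1])))))))
  expect_error(normalize_counts(tibble::tibble(mirna = "x", s1 = 0, s2 = 0)),
               "all-zero")
  expect_warning(normalize_counts(tibble::tibble(mirna = "x", s1 = 5, s2 = 0)),
                 "zero-total")
})

test_that("replicate correlation reproduces exact cases", {
  cm <- tibble::tibble(mirna = c("a", "b", "c"),
                       s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(3, 2, 1))
  expect_equal(replicate_correlation(cm, "s1", "s2"), 1)
  expect_equal(replicate_correlation(cm, "s1", "s3"), -1)
  flat <- tibble::tibble(mirna = c("a", "b", "c"), s1 = c(1, 1, 1),
                         s2 = c(1, 2, 3))
  expect_error(replicate_correlation(flat, "s1", "s2"), "variance")
})

test_that("BH adjustment equals the brute-force step-up", {
  set.seed(97)
  for (k in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("printed brain-enrichment means give a log2 fold change near -7", {
  # normalized mean 5293 in the focal tissue against 44 in the rest
  lfc <- log2_fc_rest_over_tissue(5293, 44)
  expect_equal(round(lfc), -7)
  expect_equal(lfc, log2(44 / 5293))
})

test_that("one-vs-rest exact test is symmetric and null-calibrated", {
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            tissue = c("liver", "liver", "brain", "brain"))
  cm <- toy_counts()
  names(cm) <- c("mirna", paste0("s", 1:4))
  de_l <- one_vs_rest_test(cm, samples, "liver")
  de_b <- one_vs_rest_test(cm, samples, "brain")
  # swapping group labels preserves p and negates the fold change
  expect_equal(de_l$p_value, de_b$p_value, tolerance = 1e-10)
  finite <- !de_l$fc_infinite & !de_b$fc_infinite
  expect_equal(de_l$log2_fc[finite], -de_b$log2_fc[finite], tolerance = 1e-10)
  expect_true(all(de_l$p_adj >= de_l$p_value - 1e-12))
  # identical counts in both groups: fold change 0, p near 1
  flat <- tibble::tibble(mirna = "m", s1 = 50, s2 = 60, s3 = 50, s4 = 60)
  de_f <- one_vs_rest_test(flat, samples, "liver")
  expect_equal(de_f$log2_fc, 0, tolerance = 0.05)
  expect_gt(de_f$p_value, 0.5)
  expect_error(one_vs_rest_test(cm, samples, "kidney"), "kidney")
})

test_that("tissue presence scan flags single-tissue miRNAs", {
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            tissue = c("liver", "liver", "brain", "heart"))
  cm <- tibble::tibble(mirna = c("ubiq", "liv", "zero"),
                       s1 = c(10, 4, 0), s2 = c(8, 2, 0),
                       s3 = c(5, 0, 0), s4 = c(2, 0, 0))
  scan <- tissue_presence_scan(cm, samples)
  expect_equal(scan$specific_tissue[scan$mirna == "liv"], "liver")
  expect_true(is.na(scan$specific_tissue[scan$mirna == "ubiq"]))
  expect_equal(scan$n_tissues, c(3, 1, 0))
  expect_equal(scan$tissues[[3]], character(0))
})
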