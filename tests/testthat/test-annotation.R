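test_that("duplicate resolution groups identical precursors and conserves loci", {
  prec <- tibble::tibble(
    precursor = c("AAACCC", "AAACCC", "GGGTTT", "CCCAAA"),
    contig = c("c1", "c2", "c1", "c3"), start = c(1, 500, 900, 10)
  )
  out <- resolve_duplicates(prec)
  expect_equal(out$copy_number, c(2, 2, 1, 1))
  expect_equal(out$copy_group[1], out$copy_group[2])
  expect_equal(length(unique(out$copy_group)), 3)
  sizes <- attr(out, "group_sizes")
  expect_equal(sum(sizes$copy_number * sizes$n_groups), nrow(prec))
  all_distinct <- resolve_duplicates(prec[3:4, ])
  expect_true(all(all_distinct$copy_number == 1))
})

test_that("nomenclature assigns letters, iso-miR numbers and shared names", {
  base <- tibble::tibble(
    family = "145", mature5p = "ACGTACGTACGTACGTACGTA",
    precursor = c("AAACGTACGTACGTACGTACGTAGG", "AAACGTACGTACGTACGTACGTAGC"),
    contig = c("c1", "c2"), start = c(100, 100)
  )
  # identical mature, 1-nt precursor difference: numbered iso-miR suffixes
  named <- assign_names(base)
  expect_setequal(named$name, c("ssa-mir-145-1", "ssa-mir-145-2"))
  # same family, different matures: lettered suffixes
  two_mat <- tibble::tibble(
    family = "15",
    mature5p = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTC"),
    precursor = c("p1", "p2"), contig = c("c1", "c2"), start = c(1, 1)
  )
  named2 <- assign_names(two_mat)
  expect_setequal(named2$name, c("ssa-mir-15a", "ssa-mir-15b"))
  # single unique gene: bare family name
  single <- assign_names(two_mat[1, ])
  expect_equal(single$name, "ssa-mir-15")
  # identical precursors at two loci share one name
  dup <- base
  dup$precursor <- dup$precursor[1]
  expect_equal(unique(assign_names(dup)$name), "ssa-mir-145")
  # novel genes draw fresh family numbers per distinct mature
  novel <- tibble::tibble(
    family = NA_character_,
    mature5p = c("AAAAACGTACGTACGTACGTA", "CCCCACGTACGTACGTACGTA"),
    precursor = c("px", "py"), contig = c("c1", "c2"), start = c(5, 9)
  )
  named3 <- assign_names(novel, novel_start = 9000)
  expect_setequal(named3$family, c("9000", "9001"))
})

test_that("arm dominance uses the fold-change threshold", {
  expect_equal(call_arm_dominance(2000, 100), "5p")
  expect_equal(call_arm_dominance(100, 100), "balanced")
  expect_equal(call_arm_dominance(100, 200), "3p")   # boundary at fold = 2
  expect_equal(call_arm_dominance(199, 100), "balanced")
  expect_equal(call_arm_dominance(0, 5), "3p")
  expect_equal(call_arm_dominance(c(10, 3), c(5, 9)), c("5p", "3p"))
  expect_error(call_arm_dominance(0, 0), "zero")
})

test_that("cluster detection applies the strict 10 kb same-strand rule", {
  loci <- tibble::tibble(
    name = c("g1", "g2", "g3", "g4", "g5", "g6"),
    family = c("212", "132", "30", "21", "21", "9"),
    contig = c("c1", "c1", "c1", "c2", "c2", "c2"),
    start = c(1000, 5070, 40000, 100, 10500, 30000),
    end = c(1070, 5140, 40070, 170, 10570, 30070),
    strand = c("+", "+", "+", "+", "+", "-")
  )
  cl <- detect_clusters(loci)
  # g1+g2 (4 kb apart) cluster; g3 is 34 kb away; g4+g5 gap is exactly
  # 10,330 - no wait: 10500 - 170 = 10330 >= 10000, no cluster
  expect_equal(nrow(cl), 1)
  expect_equal(cl$members[[1]]$name, c("g1", "g2"))
  expect_equal(cl$gaps[[1]], 5070 - 1070)
  # a gap of 10,001 nt (and exactly 10,000) is not a cluster
  pair <- loci[1:2, ]
  pair$start[2] <- pair$end[1] + 10001
  pair$end[2] <- pair$start[2] + 70
  expect_equal(nrow(detect_clusters(pair)), 0)
  pair$start[2] <- pair$end[1] + 10000
  pair$end[2] <- pair$start[2] + 70
  expect_equal(nrow(detect_clusters(pair)), 0)
  pair$start[2] <- pair$end[1] + 9999
  pair$end[2] <- pair$start[2] + 70
  expect_equal(nrow(detect_clusters(pair)), 1)
  # opposite strands never cluster
  pair$strand <- c("+", "-")
  expect_equal(nrow(detect_clusters(pair)), 0)
  # three genes at 3 kb and 8 kb gaps form one cluster of 3
  trio <- tibble::tibble(
    name = c("a", "b", "c"), family = "x", contig = "c9",
    start = c(100, 3270, 11440), end = c(170, 3340, 11510), strand = "+"
  )
  cl3 <- detect_clusters(trio)
  expect_equal(cl3$n_members, 3)
})

test_that("cluster membership equals pairwise chaining on random loci", {
  set.seed(83)
  n <- 200
  loci <- tibble::tibble(
    name = paste0("g", seq_len(n)),
    family = sample(c("1", "2", "3"), n, replace = TRUE),
    contig = sample(paste0("c", 1:6), n, replace = TRUE),
    start = sample.int(150000, n),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
  loci$end <- loci$start + sample(60:80, n, replace = TRUE)
  cl <- detect_clusters(loci)
  got <- lapply(cl$members, function(m) sort(m$name))
  oracle <- oracle_clusters(loci)
  oracle <- lapply(oracle[vapply(oracle, length, integer(1)) >= 2], sort)
  expect_equal(length(got), length(oracle))
  key <- function(x) paste(x, collapse = "|")
  expect_setequal(vapply(got, key, character(1)),
                  vapply(oracle, key, character(1)))
  # every locus belongs to at most one cluster
  all_members <- unlist(lapply(got, identity))
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("cluster groups key on the ordered transcription-direction signature", {
  loci <- tibble::tibble(
    name = c("a1", "b1", "a2", "b2", "b3", "a3"),
    family = c("212", "132", "212", "132", "132", "212"),
    contig = c("c1", "c1", "c2", "c2", "c3", "c3"),
    start = c(100, 4100, 900, 4900, 200, 4200),
    end = c(170, 4170, 970, 4970, 270, 4270),
    strand = c("+", "+", "+", "+", "+", "+")
  )
  cl <- detect_clusters(loci)
  gr <- group_clusters(cl)
  # c1 and c2 share (212,132); c3 has (132,212): a different ordered signature
  expect_equal(gr$n_clusters[gr$signature == "212,132"], 2)
  expect_false(is.na(gr$group_id[gr$signature == "212,132"]))
  expect_true(is.na(gr$group_id[gr$signature == "132,212"]))
  # on the minus strand the transcription order reverses the signature
  loci$strand[5:6] <- "-"
  gr2 <- group_clusters(detect_clusters(loci))
  expect_equal(gr2$n_clusters[gr2$signature == "212,132"], 3)
})

test_that("cluster conservation matches the reference by family multiset", {
  groups <- tibble::tibble(signature = c("212,132", "8000,8001", "462,731"))
  cons <- compare_cluster_conservation(groups, reference_clusters())
  expect_true(cons$conserved[1])     # the 212/132 cluster is ancient
  expect_false(cons$conserved[2])    # novel families match nothing
  expect_true(cons$conserved[3])
  empty_ref <- tibble::tibble(species = character(0), cluster = character(0),
                              members = character(0))
  cons2 <- compare_cluster_conservation(groups, empty_ref)
  expect_false(any(cons2$conserved))
  # letter/copy suffixes are harmonized away
  g2 <- tibble::tibble(signature = "212a-1,132-1")
  expect_true(compare_cluster_conservation(g2, reference_clusters())$conserved)
})
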