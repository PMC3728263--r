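# build a candidate tibble around a constructed hairpin with configurable
# read evidence
make_candidate <- function(members, seed = 11) {
  set.seed(seed)
  stem <- random_seq(28)
  loop <- random_seq(10)
  arm3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(stem)))
  substr(arm3, 15, 15) <- "A"
  hp <- paste0(stem, loop, arm3)
  flank5 <- random_seq(15)
  flank3 <- random_seq(20)
  window <- paste0(flank5, hp, flank3)
  tibble::tibble(
    candidate_id = "c1", stack_id = "s1", arm_hypothesis = "5p",
    contig = "c1", start = 1L, end = nchar(window), strand = "+",
    sequence = window, mature_start = 18L, mature_end = 39L,
    total_count = sum(members$count), members = list(members)
  )
}

consistent_members <- function() {
  tibble::tibble(
    sequence = c("m5a", "m5b", "m3"),
    start = c(18L, 18L, 60L), end = c(39L, 40L, 81L),
    count = c(1800, 150, 95)
  )
}

scattered_members <- function() {
  tibble::tibble(
    sequence = paste0("r", 1:6),
    start = c(18L, 24L, 30L, 44L, 52L, 60L),
    end = c(39L, 45L, 51L, 65L, 73L, 81L),
    count = c(400, 400, 400, 300, 300, 245)
  )
}

test_that("consistent star-supported evidence outscores scattered reads", {
  set.seed(5)
  a <- score_candidates(make_candidate(consistent_members()))
  set.seed(5)
  b <- score_candidates(make_candidate(scattered_members()))
  expect_true(a$hairpin_ok)
  expect_gt(a$total_score, b$total_score)
  # all mature reads share modal 5' ends: full consistency
  expect_equal(a$f_consistent, 1.0)
  expect_true(a$star)
  expect_equal(a$mature5p, "m5a")   # modal read becomes the mature call
})

test_that("shuffled windows lose structure score in expectation", {
  set.seed(23)
  cand <- make_candidate(consistent_members())
  real <- score_candidates(cand)
  shuf <- cand
  z_shuf <- replicate(100, {
    shuf$sequence <- shuffle_dinucleotide(cand$sequence)
    s <- score_candidates(shuf)
    if (is.finite(s$total_score)) s$z_struct else NA_real_
  })
  expect_gt(real$z_struct, mean(z_shuf, na.rm = TRUE))
  expect_gt(real$z_struct, 1)
})

test_that("calibration selects the smallest cutoff reaching the target SNR", {
  set.seed(31)
  scored <- score_candidates(make_candidate(consistent_members()))
  calib <- calibrate_cutoff(scored, n_rounds = 25, target_snr = 1)
  # degenerate target: the grid minimum qualifies immediately
  expect_equal(calib$cutoff, min(calib$table$cutoff))
  expect_false(calib$warning)
  expect_true(all(diff(calib$table$n_real) <= 0))
  # SNR arithmetic: n_real / mean permuted survivors (floored at 1/rounds)
  with_rows <- calib$table
  expect_equal(with_rows$snr,
               with_rows$n_real / pmax(with_rows$mean_n_permuted, 1 / 25))
})

test_that("raising the SNR target never increases the number of calls", {
  set.seed(37)
  scored <- purrr::map(1:6, function(i) {
    m <- consistent_members()
    m$count <- m$count * i
    s <- score_candidates(make_candidate(m, seed = i))
    s$candidate_id <- paste0("c", i)
    s
  }) |> dplyr::bind_rows()
  scored <- scored[is.finite(scored$total_score), ]
  n_called <- vapply(c(1, 5, 50), function(tgt) {
    set.seed(41)
    calib <- suppressWarnings(
      calibrate_cutoff(scored, n_rounds = 20, target_snr = tgt))
    nrow(call_candidates(scored, calib))
  }, numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("calls are inclusive at the cutoff", {
  set.seed(43)
  scored <- score_candidates(make_candidate(consistent_members()))
  expect_equal(nrow(call_candidates(scored, scored$total_score)), 1)
  expect_equal(nrow(call_candidates(scored, scored$total_score + 1e-9)), 0)
  expect_equal(nrow(call_candidates(scored[0, ], 5)), 0)
})
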