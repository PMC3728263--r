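# Exact read mapping, read-stack detection and candidate window excision.

#' Build a genome index for exact read mapping
#'
#' Precomputes the per-contig sequences and their reverse complements;
#' queries are resolved with a multi-pattern Aho-Corasick scan
#' ([Biostrings::matchPDict()]) over both strands.
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @return An object of class `mirdisc_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  assert_that(length(genome) > 0, "genome is empty")
  assert_that(!is.null(names(genome)), "genome contigs must be named")
  structure(list(genome = genome,
                 rc = Biostrings::reverseComplement(genome),
                 contig_len = setNames(Biostrings::width(genome),
                                       names(genome))),
            class = "mirdisc_index")
}

#' Map unique reads exactly to the genome
#'
#' Reports every exact-match locus of every read on both strands. Reads with
#' more than `max_loci` loci keep their locus count (the repeat rationale)
#' but are flagged for exclusion from stack formation.
#'
#' @param unique_reads Tibble with a `sequence` column ([collapse_reads()]),
#'   or a character vector of sequences.
#' @param index A `mirdisc_index` from [build_index()].
#' @param max_loci Flag threshold on the number of genomic loci.
#' @return Tibble of alignments: `sequence`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand`, `n_loci`, `flagged`.
#' @export
map_reads <- function(unique_reads, index, max_loci = 50) {
  stopifnot(inherits(index, "mirdisc_index"))
  seqs <- if (is.character(unique_reads)) unique_reads else unique_reads$sequence
  seqs <- unique(seqs)
  hits <- list()
  for (w in sort(unique(nchar(seqs)))) {
    sub <- seqs[nchar(seqs) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    for (ci in seq_along(index$genome)) {
      ctg <- names(index$genome)[ci]
      L <- index$contig_len[[ctg]]
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") index$genome[[ci]] else index$rc[[ci]]
        m <- Biostrings::matchPDict(pd, subject)
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        starts <- IRanges::start(ir)
        pat <- rep(seq_along(sub), nh)
        gstart <- if (strand == "+") starts else L - (starts + w - 1L) + 1L
        hits[[length(hits) + 1]] <- tibble(
          sequence = sub[pat], contig = ctg,
          start = gstart, end = gstart + w - 1L, strand = strand
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(sequence = character(0), contig = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  n_loci = integer(0), flagged = logical(0)))
  }
  aln <- bind_rows(hits) |>
    group_by(.data$sequence) |>
    mutate(n_loci = n()) |>
    ungroup() |>
    mutate(flagged = .data$n_loci > max_loci) |>
    arrange(.data$contig, .data$strand, .data$start)
  aln
}

#' Detect discrete read stacks
#'
#' Chains overlapping same-strand alignments into maximal stacks of span at
#' most `max_span` nt, keeping stacks whose total read count reaches
#' `min_stack_count`. Alignments flagged as multi-locus beyond the mapping
#' threshold are ignored.
#'
#' @param alignments Tibble from [map_reads()] carrying a `count` column
#'   (reads supporting each alignment in the sample under analysis).
#' @param min_stack_count Minimum total read count per stack.
#' @param max_span Maximum stack span (nt).
#' @return Tibble of stacks: `stack_id`, `contig`, `strand`, `start`, `end`,
#'   `total_count`, `modal5p` (genomic position of the modal 5' read end)
#'   and a `members` list-column of the member alignments.
#' @export
find_stacks <- function(alignments, min_stack_count = 2, max_span = 40) {
  assert_that("count" %in% names(alignments),
              "alignments need a per-sample count column")
  aln <- alignments |>
    filter(!.data$flagged, .data$count > 0) |>
    arrange(.data$contig, .data$strand, .data$start, .data$end)
  if (nrow(aln) == 0) {
    return(tibble(stack_id = character(0), contig = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  total_count = numeric(0), modal5p = integer(0),
                  members = list()))
  }
  key <- paste(aln$contig, aln$strand)
  grp <- integer(nrow(aln))
  gid <- 0L
  cur_end <- -1L
  cur_start <- -1L
  cur_key <- ""
  for (i in seq_len(nrow(aln))) {
    new_span <- max(cur_end, aln$end[i]) - cur_start + 1L
    if (key[i] != cur_key || aln$start[i] > cur_end || new_span > max_span) {
      gid <- gid + 1L
      cur_key <- key[i]
      cur_start <- aln$start[i]
      cur_end <- aln$end[i]
    } else {
      cur_end <- max(cur_end, aln$end[i])
    }
    grp[i] <- gid
  }
  aln$p5 <- ifelse(aln$strand == "+", aln$start, aln$end)
  stacks <- purrr::map(split(seq_len(nrow(aln)), grp), function(ix) {
    m <- aln[ix, ]
    agg <- tapply(m$count, m$p5, sum)
    tibble(contig = m$contig[1], strand = m$strand[1],
           start = min(m$start), end = max(m$end),
           total_count = sum(m$count),
           modal5p = as.integer(names(agg)[which.max(agg)]),
           members = list(m[, c("sequence", "start", "end", "count")]))
  }) |>
    bind_rows() |>
    filter(.data$total_count >= min_stack_count) |>
    mutate(stack_id = sprintf("stk%05d", row_number())) |>
    select("stack_id", "contig", "strand", "start", "end", "total_count",
           "modal5p", "members")
  stacks
}

#' Excise candidate precursor windows around read stacks
#'
#' Each stack yields two windows: one treating the stack as the putative 5p
#' arm (short 5' flank, long 3' flank in transcription orientation) and one
#' as the putative 3p arm. Windows are clipped at contig ends; minus-strand
#' windows are excised from the reverse complement so precursor sequences
#' always read 5' to 3'. No stack-count floor is applied beyond the one used
#' in stack detection, so every stack is excised.
#'
#' @param stacks Tibble from [find_stacks()].
#' @param index A `mirdisc_index` (or the `DNAStringSet` genome).
#' @param flank_long,flank_short Flank lengths (nt).
#' @return Tibble of candidate windows: `candidate_id`, `stack_id`,
#'   `arm_hypothesis`, `contig`, `start`, `end`, `strand`, `sequence`,
#'   `mature_start`, `mature_end` (the putative mature -- the stack's modal
#'   read -- in window coordinates, along the transcription direction),
#'   `total_count`, `members`.
#' @export
excise_candidates <- function(stacks, index, flank_long = 70,
                              flank_short = 15) {
  if (!inherits(index, "mirdisc_index")) index <- build_index(index)
  if (nrow(stacks) == 0) {
    return(tibble(candidate_id = character(0), stack_id = character(0),
                  arm_hypothesis = character(0), contig = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  sequence = character(0), mature_start = integer(0),
                  mature_end = integer(0), total_count = numeric(0),
                  members = list()))
  }
  rows <- purrr::map(seq_len(nrow(stacks)), function(i) {
    st <- stacks[i, ]
    L <- index$contig_len[[st$contig]]
    up <- list(`5p` = if (st$strand == "+") flank_short else flank_long,
               `3p` = if (st$strand == "+") flank_long else flank_short)
    # the putative mature is the modal read: anchored at the stack's modal
    # 5' end with the count-weighted modal read length (the raw stack span
    # can be wider than a mature product when loop or background fragments
    # chain into it)
    mem <- st$members[[1]]
    p5 <- if (st$strand == "+") mem$start else mem$end
    at_modal <- mem[p5 == st$modal5p, , drop = FALSE]
    lens <- at_modal$end - at_modal$start + 1L
    agg <- tapply(at_modal$count, lens, sum)
    mlen <- as.integer(names(agg)[which.max(agg)])
    if (st$strand == "+") {
      g_ms <- st$modal5p
      g_me <- st$modal5p + mlen - 1L
    } else {
      g_me <- st$modal5p
      g_ms <- st$modal5p - mlen + 1L
    }
    purrr::map(c("5p", "3p"), function(hyp) {
      us <- up[[hyp]]
      ds <- flank_long + flank_short - us
      ws <- max(1L, st$start - us)
      we <- min(L, st$end + ds)
      seq <- substr(as.character(index$genome[[st$contig]]), ws, we)
      if (st$strand == "-") seq <- revcomp(seq)
      if (st$strand == "+") {
        ms <- g_ms - ws + 1L; me <- g_me - ws + 1L
      } else {
        ms <- we - g_me + 1L; me <- we - g_ms + 1L
      }
      ms <- max(1L, ms)
      me <- min(we - ws + 1L, me)
      tibble(stack_id = st$stack_id, arm_hypothesis = hyp,
             contig = st$contig, start = ws, end = we, strand = st$strand,
             sequence = seq, mature_start = ms, mature_end = me,
             total_count = st$total_count, members = st$members)
    }) |> bind_rows()
  }) |> bind_rows()
  rows |>
    distinct(.data$contig, .data$start, .data$end, .data$strand,
             .data$mature_start, .keep_all = TRUE) |>
    mutate(candidate_id = sprintf("cand%05d", row_number())) |>
    select("candidate_id", dplyr::everything())
}
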