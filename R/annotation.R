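# Gene-level annotation: duplicate resolution, miRBase-style nomenclature,
# arm dominance, gene clusters, cross-contig cluster groups and cluster
# conservation against a reference table.

#' Group precursor loci into identical-copy groups
#'
#' Precursors at different loci with byte-identical sequences are duplicate
#' copies of one miRNA gene.
#'
#' @param precursors Tibble with at least `precursor` (sequence) and one row
#'   per genomic locus.
#' @return The input with a `copy_group` id column and `copy_number`; the
#'   attribute `"group_sizes"` holds the copy-number distribution (a tibble
#'   of `copy_number`, `n_groups`).
#' @export
resolve_duplicates <- function(precursors) {
  out <- precursors |>
    group_by(.data$precursor) |>
    mutate(copy_number = n()) |>
    ungroup() |>
    mutate(copy_group = paste0(
      "cg", match(.data$precursor, unique(.data$precursor))))
  sizes <- out |>
    distinct(.data$copy_group, .data$copy_number) |>
    count(.data$copy_number, name = "n_groups")
  attr(out, "group_sizes") <- sizes
  out
}

#' Assign miRBase-style names to classified genes
#'
#' Within a family (the conserved best-hit family, or a fresh number from
#' `novel_start` for each distinct novel mature), genes with different
#' mature sequences receive lettered suffixes (`a`, `b`, ...), identical
#' matures arising from different precursors receive numbered iso-miR
#' suffixes (`-1`, `-2`, ...), and byte-identical precursors share one
#' name. Suffixes are assigned deterministically by (contig, coordinate) of
#' each variant's first locus. A family with a single mature variant keeps
#' the bare family name; a variant with a single precursor carries no
#' number.
#'
#' @param genes Tibble with one row per locus: `family` (`NA` for novel),
#'   `precursor`, `mature5p`, `contig`, `start`.
#' @param prefix Species prefix (e.g. `"ssa"`).
#' @param novel_start First family number handed to novel genes.
#' @return The input tibble with `family` filled for novel genes and a
#'   `name` column.
#' @export
assign_names <- function(genes, prefix = "ssa", novel_start = 8000) {
  g <- genes |> mutate(.row = row_number())
  # fresh family numbers for novel genes: one family per distinct mature5p,
  # ordered by first locus
  novel <- g |> filter(is.na(.data$family))
  if (nrow(novel) > 0) {
    first_locus <- novel |>
      group_by(.data$mature5p) |>
      summarise(contig = min(.data$contig), start = min(.data$start),
                .groups = "drop") |>
      arrange(.data$contig, .data$start)
    fam_map <- setNames(as.character(novel_start - 1 +
                                       seq_len(nrow(first_locus))),
                        first_locus$mature5p)
    g$family[is.na(g$family)] <- fam_map[novel$mature5p]
  }
  named <- g |>
    group_by(.data$family) |>
    dplyr::group_modify(function(fam, key) {
      # letter per distinct mature, ordered by first locus
      mat_order <- fam |>
        group_by(.data$mature5p) |>
        summarise(contig = min(.data$contig), start = min(.data$start),
                  .groups = "drop") |>
        arrange(.data$contig, .data$start)
      n_mat <- nrow(mat_order)
      letter <- setNames(if (n_mat > 1) letters[seq_len(n_mat)] else "",
                         mat_order$mature5p)
      fam |>
        group_by(.data$mature5p) |>
        dplyr::group_modify(function(var, vkey) {
          prec_order <- var |>
            group_by(.data$precursor) |>
            summarise(contig = min(.data$contig), start = min(.data$start),
                      .groups = "drop") |>
            arrange(.data$contig, .data$start)
          num <- setNames(
            if (nrow(prec_order) > 1) paste0("-", seq_len(nrow(prec_order)))
            else "",
            prec_order$precursor)
          mutate(var, suffix_num = num[.data$precursor])
        }) |>
        ungroup() |>
        mutate(suffix_letter = letter[.data$mature5p])
    }) |>
    ungroup() |>
    mutate(name = paste0(prefix, "-mir-", .data$family, .data$suffix_letter,
                         .data$suffix_num)) |>
    arrange(.data$.row) |>
    select(-".row", -"suffix_letter", -"suffix_num")
  dup <- named |> distinct(.data$name, .data$precursor)
  if (anyDuplicated(dup$name) > 0) {
    stop("internal error: name collision across distinct precursors",
         call. = FALSE)
  }
  named
}

#' Call arm dominance from 5p and 3p read counts
#'
#' @param counts5p,counts3p Read counts per arm (vectors recycle).
#' @param fold Dominance threshold: an arm dominates when its count is at
#'   least `fold` times the other arm's.
#' @return Character vector: `"5p"`, `"3p"` or `"balanced"`.
#' @export
call_arm_dominance <- function(counts5p, counts3p, fold = 2) {
  assert_that(all(counts5p >= 0) && all(counts3p >= 0),
              "counts must be non-negative")
  assert_that(all(counts5p + counts3p > 0),
              "counts5p and counts3p must not both be zero")
  dplyr::case_when(
    counts5p >= fold * counts3p ~ "5p",
    counts3p >= fold * counts5p ~ "3p",
    TRUE ~ "balanced"
  )
}

#' Detect miRNA gene clusters
#'
#' Two or more precursor loci on the same contig and strand, with
#' consecutive gaps (end of the upstream precursor to start of the
#' downstream one) of less than `max_gap` nt, form a gene cluster.
#' Singletons are not clusters. Members are ordered along the transcription
#' direction (reversed genomic order on the minus strand).
#'
#' @param loci Tibble with `name`, `contig`, `start`, `end`, `strand` and
#'   optionally `family`.
#' @param max_gap Gap threshold in nt (exclusive).
#' @return Tibble: `cluster_id`, `contig`, `strand`, `start`, `end`,
#'   `n_members`, `members` (list-column of member tibbles in transcription
#'   order) and `gaps` (list-column of consecutive genomic gaps).
#' @export
detect_clusters <- function(loci, max_gap = 10000) {
  if (!"family" %in% names(loci)) loci$family <- NA_character_
  srt <- arrange(loci, .data$contig, .data$strand, .data$start)
  n <- nrow(srt)
  if (n == 0) {
    return(tibble(cluster_id = character(0), contig = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  n_members = integer(0), members = list(), gaps = list()))
  }
  grp <- integer(n)
  gid <- 0L
  max_end <- -Inf
  for (i in seq_len(n)) {
    new_chain <- i == 1 ||
      srt$contig[i] != srt$contig[i - 1] ||
      srt$strand[i] != srt$strand[i - 1] ||
      (srt$start[i] - max_end) >= max_gap
    if (new_chain) {
      gid <- gid + 1L
      max_end <- srt$end[i]
    } else {
      max_end <- max(max_end, srt$end[i])
    }
    grp[i] <- gid
  }
  chains <- split(seq_len(n), grp)
  chains <- chains[vapply(chains, length, integer(1)) >= 2]
  if (length(chains) == 0) {
    return(tibble(cluster_id = character(0), contig = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  n_members = integer(0), members = list(), gaps = list()))
  }
  purrr::map(chains, function(ix) {
    m <- srt[ix, ]
    gaps <- m$start[-1] - m$end[-nrow(m)]
    if (m$strand[1] == "-") m <- m[rev(seq_len(nrow(m))), ]
    tibble(contig = m$contig[1], strand = m$strand[1],
           start = min(m$start), end = max(m$end), n_members = nrow(m),
           members = list(m), gaps = list(gaps))
  }) |>
    bind_rows() |>
    mutate(cluster_id = sprintf("cluster%03d", row_number())) |>
    select("cluster_id", "contig", "strand", "start", "end", "n_members",
           "members", "gaps")
}

# ordered family signature of a cluster, along the transcription direction
cluster_signature <- function(cluster_members) {
  paste(cluster_members$family, collapse = ",")
}

#' Group gene clusters by family composition across contigs
#'
#' Clusters sharing the same ordered family signature along the
#' transcription direction form a cluster group. Groups with at least two
#' member clusters receive roman-numeral ids; clusters whose signature is
#' seen on one contig only are listed as singletons.
#'
#' @param clusters Tibble from [detect_clusters()] (members must carry a
#'   `family` column).
#' @return Tibble: `group_id` (`NA` for singletons), `signature`,
#'   `n_clusters`, `cluster_ids` (list-column), `contigs` (list-column).
#' @export
group_clusters <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(tibble(group_id = character(0), signature = character(0),
                  n_clusters = integer(0), cluster_ids = list(),
                  contigs = list()))
  }
  sig <- vapply(clusters$members, cluster_signature, character(1))
  tab <- tibble(cluster_id = clusters$cluster_id, contig = clusters$contig,
                signature = sig) |>
    group_by(.data$signature) |>
    summarise(n_clusters = n(), cluster_ids = list(.data$cluster_id),
              contigs = list(.data$contig), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_clusters), .data$signature)
  multi <- tab$n_clusters >= 2
  tab$group_id <- NA_character_
  tab$group_id[multi] <- as.character(utils::as.roman(seq_len(sum(multi))))
  select(tab, "group_id", "signature", "n_clusters", "cluster_ids", "contigs")
}

#' Compare cluster groups to a reference cluster table
#'
#' A cluster (or group signature) is conserved when its family multiset is
#' contained in some reference cluster's family multiset, after harmonizing
#' names to family cores (letter and copy suffixes stripped).
#'
#' @param groups Tibble from [group_clusters()] (or any tibble with a
#'   `signature` column of comma-separated family names).
#' @param reference Tibble with columns `species`, `cluster` and `members`
#'   (comma-separated member names), e.g. [reference_clusters()].
#' @return `groups` with `conserved` (logical), `matched_species` and
#'   `matched_cluster` columns.
#' @export
compare_cluster_conservation <- function(groups, reference) {
  ref_sets <- purrr::map(strsplit(reference$members, ","), function(m) {
    normalize_family_label(trimws(m))
  })
  res <- purrr::map(groups$signature, function(sig) {
    fams <- normalize_family_label(trimws(strsplit(sig, ",")[[1]]))
    hit <- NA_integer_
    for (k in seq_along(ref_sets)) {
      # sub-multiset test
      tf <- table(fams)
      tr <- table(ref_sets[[k]])
      if (all(names(tf) %in% names(tr)) &&
          all(tf <= tr[names(tf)])) {
        hit <- k
        break
      }
    }
    tibble(conserved = !is.na(hit),
           matched_species = if (is.na(hit)) NA_character_ else
             reference$species[hit],
           matched_cluster = if (is.na(hit)) NA_character_ else
             reference$cluster[hit])
  }) |> bind_rows()
  bind_cols(groups, res)
}

# Normalize a miRNA family label to its core: drop species/mir prefixes,
# lettered variants and numbered copy suffixes. "let" families keep the
# let-7 stem.
normalize_family_label <- function(x) {
  x <- trimws(x)
  x <- sub("^[A-Za-z]{3,4}-", "", x)
  is_let <- grepl("^let", x, ignore.case = TRUE) | grepl("^7\\s*[a-z]", x)
  x <- sub("^(mir|miR|let)[-:]?\\s*", "", x, ignore.case = TRUE)
  core <- sub("^\\s*([0-9]+).*$", "\\1", x)
  ifelse(is_let, "let-7", core)
}
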