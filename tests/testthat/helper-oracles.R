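# Independent oracles: brute-force structure enumeration, recursive local
# alignment, pairwise cluster chaining, step-up BH.

oracle_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA")) return(2)
  if (key %in% c("GT", "TG")) return(1)
  -1
}

# exhaustive enumeration of all nested structures (hairpin loops >= 3 nt),
# scoring pair weights plus +1 per stacked pair; feasible for length <= 12
oracle_fold_score <- function(seq) {
  ch <- strsplit(toupper(chartr("uU", "tT", seq)), "")[[1]]
  n <- length(ch)
  structs <- function(i, j) {
    if (j - i < 4) return(list(list()))
    res <- structs(i + 1, j)
    for (k in (i + 4):j) {
      if (oracle_pair_weight(ch[i], ch[k]) > 0) {
        inner <- structs(i + 1, k - 1)
        outer <- structs(k + 1, j)
        for (a in inner) {
          for (b in outer) {
            res[[length(res) + 1]] <- c(list(c(i, k)), a, b)
          }
        }
      }
    }
    res
  }
  best <- 0
  for (s in structs(1, n)) {
    if (length(s) == 0) next
    prs <- do.call(rbind, s)
    sc <- sum(vapply(seq_len(nrow(prs)), function(r) {
      oracle_pair_weight(ch[prs[r, 1]], ch[prs[r, 2]])
    }, numeric(1)))
    keys <- paste(prs[, 1], prs[, 2])
    sc <- sc + sum(paste(prs[, 1] + 1, prs[, 2] - 1) %in% keys)
    best <- max(best, sc)
  }
  best
}

# independent top-down recursive local alignment with affine gaps: best
# global alignment over all substring pairs, memoized recursion
oracle_local_align <- function(q, s, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  qc <- strsplit(toupper(q), "")[[1]]
  sc <- strsplit(toupper(s), "")[[1]]
  m <- length(qc); n <- length(sc)
  memo <- new.env(parent = emptyenv())
  # best score of an alignment path starting at (i, j) in given state and
  # ending anywhere (local suffix maximum), state: 0 = match, 1/2 = in gap
  rec <- function(i, j, state) {
    if (i > m || j > n) return(0)
    key <- paste(i, j, state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    sub <- if (qc[i] == sc[j]) match else mismatch
    best <- 0
    best <- max(best, sub + rec(i + 1, j + 1, 0))
    gq <- if (state == 1) gap_extend else gap_open
    gs <- if (state == 2) gap_extend else gap_open
    best <- max(best, gq + rec(i + 1, j, 1))
    best <- max(best, gs + rec(i, j + 1, 2))
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- max(best, rec(i, j, 0))
    }
  }
  best
}

# pairwise O(n^2) chaining: connected components of loci with same contig
# and strand and end-to-start gap below max_gap
oracle_clusters <- function(loci, max_gap = 10000) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a >= b) next
      if (loci$contig[a] != loci$contig[b] ||
          loci$strand[a] != loci$strand[b]) next
      gap <- max(loci$start[a], loci$start[b]) -
        min(loci$end[a], loci$end[b])
      if (gap < max_gap) parent[find(a)] <- find(b)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(loci$name, comp)
}

# step-up Benjamini-Hochberg by direct construction
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (r in seq_len(n)) {
    adj[o[r]] <- min(1, min(p[o][r:n] * n / (r:n)))
  }
  adj
}

oracle_dinuc_counts <- function(seq) {
  seq <- toupper(chartr("uU", "tT", seq))
  n <- nchar(seq)
  sort(table(substring(seq, 1:(n - 1), 2:n)))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
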