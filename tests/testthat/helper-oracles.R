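# Independent oracles used across test files. Each is deliberately naive
# (brute force / closed form) and shares no code with the implementation
# it checks.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_copy <- function(seed, rate) {
  v <- strsplit(seed, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive O(n*m) sliding-window motif scan on both strands (exact motifs only)
naive_scan <- function(seq, motif) {
  m <- nchar(motif)
  rcm <- rc_oracle(motif)
  out <- list()
  for (i in seq_len(nchar(seq) - m + 1)) {
    piece <- substr(seq, i, i + m - 1)
    if (piece == motif) out[[length(out) + 1]] <- c(i - 1L, "+")
    if (piece == rcm) out[[length(out) + 1]] <- c(i - 1L, "-")
  }
  if (!length(out)) {
    return(data.frame(offset = integer(0), strand = character(0)))
  }
  df <- data.frame(offset = as.integer(sapply(out, `[`, 1)),
                   strand = sapply(out, `[`, 2), stringsAsFactors = FALSE)
  df[order(df$offset, df$strand), , drop = FALSE]
}

# brute-force enumeration of ordered-subsequence grammar matches over
# window-mapped repeats (data.frame with wstart, wend, wstrand,
# class_family, sorted by wstart)
brute_matches <- function(wr, terms, max_gap, orientation = "any") {
  k <- length(terms)
  n <- nrow(wr)
  if (n < k) return(list())
  combos <- utils::combn(n, k, simplify = FALSE)
  out <- list()
  for (cb in combos) {
    # every permutation-free ordered pick = the combo in sorted-row order;
    # but distinct rows may share wstart, so enforce strict start increase
    cb <- cb[order(wr$wstart[cb], wr$wend[cb])]
    if (any(wr$class_family[cb] != terms)) next
    if (k > 1) {
      starts <- wr$wstart[cb]
      ends <- wr$wend[cb]
      if (any(diff(starts) <= 0)) next
      if (any(starts[-1] - ends[-k] > max_gap)) next
    }
    if (orientation == "same_strand" && length(unique(wr$wstrand[cb])) > 1) next
    out[[length(out) + 1]] <- cb
  }
  out
}

# exhaustive enumeration of all global alignments of two short sequences,
# returning the maximum score (for <= 5-mers)
exhaustive_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      s <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(va)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(vb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# brute-force two-sample KS statistic: max ECDF gap over a value grid
brute_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

# all multisets of size n over values 1:3, as sorted vectors
multisets3 <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) {
    out[[length(out) + 1]] <- rep(1:3, c(a, b, n - a - b))
  }
  out
}

# random unrooted binary tree with positive branch lengths and its
# additive distance matrix (taxa in sorted label order)
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# a small simulated scan scene shared by io/scan tests
small_sim <- function(seed = 1, n_genes = 12L, n_planted_configs = 4L,
                      chrom_length = 80000L, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    n_planted_configs = n_planted_configs,
                    chrom_length = chrom_length, ...)
  simulate_genome(cfg)
}

empty_repeats_df <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), name = character(0),
             class_family = character(0), stringsAsFactors = FALSE)
}
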