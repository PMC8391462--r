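# Consensus/phylogeny stage: redundancy collapse, star multiple alignment,
# consensus + position frequency matrix, p-distances, Neighbor-Joining, and
# nearest-subfamily assignment. The alignment and NJ algorithms are
# implemented here (deterministic, exactly testable); ape is used only as a
# container/serializer for trees.

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under a linear gap penalty. Traceback ties are
#' broken by preferring the diagonal move, then the vertical (gap in `b`),
#' then the horizontal (gap in `a`), which makes the alignment string — not
#' just the score — deterministic.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap scoring scheme; `N` against anything scores as
#'   a mismatch.
#' @return list with `aligned_a`, `aligned_b` (equal-length strings over
#'   `{A,C,G,T,N,-}`) and integer `score`.
#' @export
#' @examples
#' align_pair("ACGT", "ACT")$score  # 1
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  va <- chars(a); vb <- chars(b)
  n <- length(va); m <- length(vb)
  # substitution scores for every pair of positions; N scores as mismatch
  eq <- outer(va, vb, "==")
  if (any(va == "N")) eq[va == "N", ] <- FALSE
  if (any(vb == "N")) eq[, vb == "N"] <- FALSE
  subM <- mismatch + (match - mismatch) * eq
  M <- matrix(0, n + 1, m + 1)
  M[1, ] <- gap * (0:m)
  M[, 1] <- gap * (0:n)
  jj <- seq_len(m)
  gj <- gap * jj
  for (i in seq_len(n)) {
    # candidates from the previous row (diagonal and vertical)
    A <- pmax(M[i, jj] + subM[i, ], M[i, jj + 1] + gap)
    # horizontal moves form a running max under linear gaps:
    # M[i+1, j] = gap*j + cummax over k <= j of (A_k - gap*k), seeded by the
    # all-gap prefix M[i+1, 0]
    u <- cummax(c(M[i + 1, 1], A - gj))
    M[i + 1, jj + 1] <- gj + u[jj + 1]
  }
  # traceback with the documented tie order, filled right to left
  ra <- character(n + m); rb <- character(n + m)
  k <- n + m + 1L
  i <- n; j <- m
  while (i > 0 || j > 0) {
    k <- k - 1L
    if (i > 0 && j > 0 && M[i + 1, j + 1] == M[i, j] + subM[i, j]) {
      ra[k] <- va[i]; rb[k] <- vb[j]; i <- i - 1; j <- j - 1
    } else if (i > 0 && M[i + 1, j + 1] == M[i, j + 1] + gap) {
      ra[k] <- va[i]; rb[k] <- "-"; i <- i - 1
    } else {
      ra[k] <- "-"; rb[k] <- vb[j]; j <- j - 1
    }
  }
  idx <- k:(n + m)
  list(aligned_a = paste(ra[idx], collapse = ""),
       aligned_b = paste(rb[idx], collapse = ""),
       score = M[n + 1, m + 1])
}

# fraction of identical columns over the full alignment length
alignment_identity <- function(aln) {
  x <- chars(aln$aligned_a); y <- chars(aln$aligned_b)
  mean(x == y & x != "-")
}

#' Collapse near-identical sequences to representatives
#'
#' Greedy clustering in input order: each sequence joins the first existing
#' cluster whose representative it matches at `>= identity_threshold` global
#' identity (identical columns / alignment length under [align_pair()]);
#' otherwise it founds a new cluster. Representatives are the first member
#' of each cluster, in input order — a deduplication pass, deterministic by
#' construction.
#'
#' @param sequences character vector (optionally named).
#' @param identity_threshold in `(0, 1]`.
#' @return list with `representatives` (character vector) and `cluster`
#'   (integer vector assigning each input to a representative).
#' @export
collapse_redundancy <- function(sequences, identity_threshold = 0.95) {
  stopifnot(length(sequences) >= 1)
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  reps <- integer(0)
  cluster <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      idn <- alignment_identity(align_pair(sequences[[reps[k]]], sequences[[i]]))
      if (idn >= identity_threshold) {
        cluster[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  list(representatives = sequences[reps], cluster = cluster,
       representative_index = reps)
}

#' Star multiple alignment
#'
#' Center sequence = the one maximizing summed pairwise identity to all
#' others (ties to the first); every other sequence is aligned to the center
#' pairwise and gaps are merged under the once-a-gap-always-a-gap rule. A
#' single input sequence is returned as a 1-row alignment with a warning.
#'
#' @param sequences character vector.
#' @return list with `rows` (equal-length aligned strings, input order) and
#'   `center` (index of the center sequence).
#' @export
build_msa <- function(sequences) {
  k <- length(sequences)
  if (k == 1) {
    warning("single sequence: returning trivial 1-row alignment")
    return(list(rows = as.character(sequences), center = 1L))
  }
  idsum <- numeric(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    idn <- alignment_identity(align_pair(sequences[[i]], sequences[[j]]))
    idsum[i] <- idsum[i] + idn
    idsum[j] <- idsum[j] + idn
  }
  center <- which.max(idsum)
  cseq <- sequences[[center]]
  L <- nchar(cseq)
  # pairwise-align each non-center row to the center; record, for each
  # center position, how many inserted characters precede it
  pair <- vector("list", k)
  ins <- matrix(0L, k, L + 1)  # insertions before center position c (and after end)
  for (i in seq_len(k)) {
    if (i == center) next
    al <- align_pair(cseq, sequences[[i]])
    pair[[i]] <- al
    ca <- chars(al$aligned_a)
    pos <- 1L
    for (col in seq_along(ca)) {
      if (ca[col] == "-") ins[i, pos] <- ins[i, pos] + 1L else pos <- pos + 1L
    }
  }
  maxins <- apply(ins, 2, max)
  pad <- function(n) strrep("-", n)
  rows <- character(k)
  # center row: gaps wherever any sequence inserted
  cch <- chars(cseq)
  rows[center] <- paste0(paste0(pad(maxins[seq_len(L)]), cch, collapse = ""),
                         pad(maxins[L + 1]))
  for (i in seq_len(k)) {
    if (i == center) next
    al <- pair[[i]]
    ca <- chars(al$aligned_a); cb <- chars(al$aligned_b)
    out <- character(0)
    pos <- 1L; col <- 1L
    ncol_aln <- length(ca)
    for (p in seq_len(L + 1)) {
      # emit this row's insertions before center position p, padded to maxins
      piece <- character(0)
      while (col <= ncol_aln && ca[col] == "-") {
        piece <- c(piece, cb[col]); col <- col + 1L
      }
      out <- c(out, pad(maxins[p] - length(piece)), piece)
      if (p <= L) {  # the aligned character at center position p
        out <- c(out, cb[col]); col <- col + 1L
      }
    }
    rows[i] <- paste(out, collapse = "")
  }
  stopifnot(length(unique(nchar(rows))) == 1)
  list(rows = rows, center = center)
}

#' Consensus, position frequency matrix and information content of an MSA
#'
#' Columns whose gap fraction exceeds `gap_column_threshold` are dropped.
#' Per retained column the consensus base is the majority over `{A,C,G,T}`
#' (ties broken alphabetically) and the information content is
#' `2 - H` bits, where `H` is the Shannon entropy of the base frequencies
#' with gaps excluded.
#'
#' @param msa list as returned by [build_msa()], or a character vector of
#'   equal-length aligned rows.
#' @param gap_column_threshold columns with gap fraction strictly above this
#'   are dropped.
#' @return list with `consensus` (string), `pfm` (5 x L counts over
#'   `A,C,G,T,-`) and `info_content` (numeric, bits in `[0, 2]`).
#' @export
call_consensus <- function(msa, gap_column_threshold = 0.5) {
  rows <- if (is.list(msa)) msa$rows else msa
  stopifnot(length(rows) >= 1, length(unique(nchar(rows))) == 1)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  letters5 <- c(DNA_BASES, "-")
  pfm <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = letters5), nbins = 5)
  })
  rownames(pfm) <- letters5
  gapfrac <- pfm["-", ] / nrow(mat)
  keep <- which(gapfrac <= gap_column_threshold)
  if (!length(keep)) stop("all columns dropped by gap_column_threshold")
  pfm <- pfm[, keep, drop = FALSE]
  base_counts <- pfm[DNA_BASES, , drop = FALSE]
  cons <- apply(base_counts, 2, function(cnt) {
    DNA_BASES[which.max(cnt)]  # which.max takes the first = alphabetical tie-break
  })
  info <- apply(base_counts, 2, function(cnt) {
    p <- cnt / sum(cnt)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(consensus = paste(cons, collapse = ""), pfm = pfm, info_content = info)
}

# p-distance between two aligned rows: mismatches / sites where both non-gap
p_distance_aligned <- function(ra, rb) {
  x <- chars(ra); y <- chars(rb)
  ok <- x != "-" & y != "-"
  if (!any(ok)) stop("no comparable (both non-gap) sites for this pair")
  mean(x[ok] != y[ok])
}

# Kimura 2-parameter distance between two aligned rows
k2p_distance_aligned <- function(ra, rb) {
  x <- chars(ra); y <- chars(rb)
  ok <- x != "-" & y != "-" & x %in% DNA_BASES & y %in% DNA_BASES
  if (!any(ok)) stop("no comparable sites for this pair")
  x <- x[ok]; y <- y[ok]
  purine <- c("A", "G")
  transition <- x != y & (x %in% purine) == (y %in% purine)
  transversion <- x != y & !transition
  P <- mean(transition); Q <- mean(transversion)
  val <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (val <= 0) stop("K2P distance undefined (saturated pair)")
  -0.5 * log(val)
}

#' Pairwise distance matrix (p-distance, or K2P behind a flag)
#'
#' Accepts either an MSA (all pairs compared on shared columns) or raw
#' sequences (each pair globally aligned first with [align_pair()]).
#'
#' @param x [build_msa()] result, character vector of aligned rows of equal
#'   length, or named character vector of unaligned sequences.
#' @param labels taxon labels; defaults to names of `x` or `seq1..seqN`.
#' @param model `"p"` (proportion of differing sites) or `"k2p"`.
#' @param aligned treat the rows as already aligned (columns compared
#'   as-is) instead of globally aligning each pair first; the default
#'   treats equal-length inputs as aligned, as MSA rows always are.
#' @return symmetric numeric matrix with zero diagonal, dimnames = labels.
#' @export
p_distance_matrix <- function(x, labels = NULL, model = c("p", "k2p"),
                              aligned = NULL) {
  model <- match.arg(model)
  rows <- if (is.list(x)) x$rows else x
  stopifnot(length(rows) >= 2)
  if (is.null(aligned)) aligned <- length(unique(nchar(rows))) == 1
  if (is.null(labels)) {
    labels <- names(rows)
    if (is.null(labels)) labels <- paste0("seq", seq_along(rows))
  }
  n <- length(rows)
  distfun <- if (model == "p") p_distance_aligned else k2p_distance_aligned
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (aligned) {
      d <- distfun(rows[i], rows[j])
    } else {
      al <- align_pair(rows[[i]], rows[[j]])
      d <- distfun(al$aligned_a, al$aligned_b)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined (ties broken by the lowest
#' (row, column) index pair), branch lengths come from the standard NJ
#' formulas, and the final three nodes are joined at an unrooted
#' trifurcation. Negative branch-length estimates are clamped to zero and
#' counted in `n_clamped`.
#'
#' @param D symmetric non-negative distance matrix with labelled dimnames,
#'   `n >= 3` taxa.
#' @return list with `newick` (string), `tree` (an `ape::phylo`) and
#'   `n_clamped` (number of negative branch lengths clamped to 0).
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3, ncol(D) == n)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  node <- as.list(labels)  # newick fragment per active node
  clamped <- 0L
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) formatC(x, format = "g", digits = 12)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (row, column) with i < j among the minima
    Q[lower.tri(Q)] <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- bl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- bl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", node[[i]], ":", fmt(li), ",", node[[j]], ":",
                     fmt(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
                c(newdist[keep], 0))
    D <- D2
    node <- c(node[keep], merged)
  }
  # three remaining nodes joined at the unrooted center
  la <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", node[[1]], ":", fmt(la), ",", node[[2]], ":",
                   fmt(lb2), ",", node[[3]], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = newick)
  list(newick = newick, tree = tree, n_clamped = clamped)
}

#' Assign a sequence to its nearest subfamily consensus
#'
#' The candidate is globally aligned to every consensus in the library; the
#' assignment is the minimum p-distance (ties broken by alphabetical
#' subfamily name). For reporting, the NJ tree of the candidate plus all
#' library consensi is returned alongside.
#'
#' @param candidate DNA string.
#' @param consensus_library named character vector of subfamily consensi.
#' @param candidate_label leaf label for the candidate in the placement tree.
#' @return list with `subfamily`, `distance`, `all_distances` and
#'   `placement` (an [nj_tree()] result, `NULL` when the library has < 2
#'   entries).
#' @export
assign_subfamily <- function(candidate, consensus_library,
                             candidate_label = "candidate") {
  stopifnot(length(consensus_library) >= 1)
  nm <- names(consensus_library)
  d <- vapply(seq_along(consensus_library), function(k) {
    al <- align_pair(candidate, consensus_library[[k]])
    p_distance_aligned(al$aligned_a, al$aligned_b)
  }, numeric(1))
  names(d) <- nm
  best <- sort(nm[d == min(d)])[1]
  placement <- NULL
  if (length(consensus_library) >= 2) {
    seqs <- c(stats::setNames(candidate, candidate_label), consensus_library)
    placement <- nj_tree(p_distance_matrix(seqs, aligned = FALSE))
  }
  list(subfamily = best, distance = unname(d[best]), all_distances = d,
       placement = placement)
}
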