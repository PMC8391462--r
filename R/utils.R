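#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pchisq pt qnorm rbinom rexp rnorm runif sd cor
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Operates on plain uppercase character strings over `{A,C,G,T,N}` and the
#' IUPAC ambiguity codes; `N` maps to `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGACCTC")  # "GAGGTCA"
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# 0-based half-open interval overlap in bp
overlap_bp <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# random DNA string of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute bases at per-site probability `rate`; substitution-only,
# each mutated site gets one of the three other bases uniformly
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- chars(seq)
  hit <- which(runif(length(v)) < rate & v %in% DNA_BASES)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1))
  }
  paste(v, collapse = "")
}

# replace seq[at .. at+nchar(piece)-1] (1-based) with piece
splice_into <- function(seq, piece, at) {
  stopifnot(at >= 1, at + nchar(piece) - 1 <= nchar(seq))
  paste0(substr(seq, 1, at - 1), piece, substr(seq, at + nchar(piece), nchar(seq)))
}
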