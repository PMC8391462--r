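# Builds the bundled SYNTHETIC Alu subfamily consensus library:
# four ~300 bp "subfamily" consensi derived from one random ancestor at
# 5-15% divergence. These are stand-ins with the statistical shape of Alu
# subfamily consensi (length, mutual divergence), not real Repbase entries;
# filenames and headers say so. Consensi are rejected/resampled until none
# contains the PPRE heptamer TGACCTC on either strand, so planted motifs
# are the only ones inside simulated Alu copies.
set.seed(20260924)
bases <- c("A", "C", "G", "T")
L <- 300L
motifs <- c("TGACCTC", "GAGGTCA")
has_motif <- function(s) any(vapply(motifs, grepl, logical(1), x = s, fixed = TRUE))
diverge <- function(anc, rate) {
  repeat {
    v <- strsplit(anc, "")[[1]]
    hit <- which(runif(L) < rate)
    for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1)
    s <- paste(v, collapse = "")
    if (!has_motif(s)) return(s)
  }
}
repeat {
  anc <- paste(sample(bases, L, replace = TRUE), collapse = "")
  if (!has_motif(anc)) break
}
lib <- c(
  AluJ_syn  = diverge(anc, 0.15),
  AluSx_syn = diverge(anc, 0.08),
  AluSz_syn = diverge(anc, 0.10),
  AluY_syn  = diverge(anc, 0.05)
)
out <- "inst/extdata/alu_subfamily_consensus_synthetic.fasta"
con <- file(out, "w")
for (nm in names(lib)) {
  writeLines(c(paste0(">", nm, " synthetic Alu subfamily consensus (not a Repbase sequence)"),
               substring(lib[[nm]], seq(1, L, 70), pmin(seq(1, L, 70) + 69, L))), con)
}
close(con)
cat("wrote", out, "\n")
# report mutual p-distances for the record
pd <- function(a, b) mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
nm <- names(lib)
for (i in 1:3) for (j in (i + 1):4)
  cat(sprintf("%s vs %s: %.3f\n", nm[i], nm[j], pd(lib[[i]], lib[[j]])))
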