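# Synthetic inputs with planted ground truth: a genome whose promoters carry
# the ordered repeat configuration Alu-Alu-Low_complexity-LINE/L1 with a
# PPRE heptamer written into the left arm of the first Alu next to its
# B-box; two-gene expression cohorts with a set population correlation;
# observed/null variant-score sets; and survival cohorts whose hazard
# depends on an expression group. Everything is reproducible byte-for-byte
# from the seed.

PPRE_MOTIF <- "TGACCTC"

#' Simulation configuration with validated defaults
#'
#' Defaults encode the study conditions emulated throughout: 4 kb promoter
#' windows, ~300 bp Alu copies, a `(TA)n` low-complexity run and an L1
#' fragment with inter-element gaps of at most 500 bp; an 80-case survival
#' cohort split 49 disomy 3 / 31 monosomy 3 with the high-expression group
#' at lower hazard; tumor/control expression pairs with strong control and
#' weak tumor correlation; and an observed mutation set of 107 draws
#' enriched in the 60-80 score band over an all-missense null.
#'
#' @param seed integer RNG seed; same config => byte-identical outputs.
#' @param chrom_length simulated contig length (bp).
#' @param n_genes number of genes (TSS records).
#' @param n_planted_configs how many genes receive a planted configuration.
#' @param alu_mutation_rate per-base substitution probability for planted
#'   Alu copies, in `[0, 1)`.
#' @param intergene_spacing bp between consecutive promoter slots.
#' @param window_length promoter window length used for planting.
#' @param max_gap largest inter-element gap drawn when planting (bp).
#' @param ppre_offset consensus offset at which the PPRE heptamer is
#'   written into the first Alu's left arm (default 62: the heptamer ends
#'   3 bp before the default B-box start at 72).
#' @param expression list: `n_tumor`, `n_control`, `r_tumor`, `r_control`.
#' @param mutations list: `n_observed`, `score_band` (length-2 in
#'   `[0,100]`), `band_fraction` in `[0,1]`.
#' @param survival list: `n_cases`, `frac_monosomy3`, `hazard_low`,
#'   `hazard_high` (per unit time, for the low/high expression groups),
#'   `censor_time`, and optional `hazard_low_m3`/`hazard_high_m3` overrides
#'   for the monosomy 3 stratum.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 300000L,
                       n_genes = 50L,
                       n_planted_configs = 10L,
                       alu_mutation_rate = 0,
                       intergene_spacing = 1000L,
                       window_length = 4000L,
                       max_gap = 500L,
                       ppre_offset = 62L,
                       expression = list(),
                       mutations = list(),
                       survival = list()) {
  expression <- modifyList(
    list(n_tumor = 300L, n_control = 50L, r_tumor = 0.2, r_control = 0.8),
    expression)
  mutations <- modifyList(
    list(n_observed = 107L, score_band = c(60, 80), band_fraction = 0.4),
    mutations)
  survival <- modifyList(
    list(n_cases = 80L, frac_monosomy3 = 31 / 80, hazard_low = 0.03,
         hazard_high = 0.01, censor_time = 60,
         hazard_low_m3 = NULL, hazard_high_m3 = NULL),
    survival)
  cfg <- list(seed = as.integer(seed), chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_planted_configs = as.integer(n_planted_configs),
              alu_mutation_rate = alu_mutation_rate,
              intergene_spacing = as.integer(intergene_spacing),
              window_length = as.integer(window_length),
              max_gap = as.integer(max_gap),
              ppre_offset = as.integer(ppre_offset),
              expression = expression, mutations = mutations,
              survival = survival)
  stopifnot(cfg$n_genes >= 0, cfg$n_planted_configs >= 0,
            cfg$n_planted_configs <= cfg$n_genes,
            cfg$alu_mutation_rate >= 0, cfg$alu_mutation_rate < 1,
            cfg$max_gap >= 1)
  if (abs(expression$r_tumor) >= 1 || abs(expression$r_control) >= 1) {
    stop("expression correlations must lie strictly inside (-1, 1)")
  }
  stopifnot(mutations$band_fraction >= 0, mutations$band_fraction <= 1,
            length(mutations$score_band) == 2,
            mutations$score_band[1] >= 0, mutations$score_band[2] <= 100,
            survival$hazard_low > 0, survival$hazard_high > 0,
            survival$censor_time > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Bundled synthetic Alu subfamily consensus library
#'
#' Four ~300 bp synthetic "subfamily" consensi (5-15% mutual divergence
#' from a shared ancestor), shipped with the package; a real consensus
#' FASTA may be supplied instead via `path`.
#'
#' @param path optional FASTA of consensus sequences to use instead.
#' @return named character vector of uppercase consensus strings.
#' @export
alu_consensus_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "alu_subfamily_consensus_synthetic.fasta",
                        package = "ppreAlu")
  }
  read_genome_fasta(path)
}

#' Simulate a genome with planted promoter repeat configurations
#'
#' The background sequence is i.i.d. uniform over `ACGT`. Each of
#' `n_planted_configs` randomly chosen genes receives, inside its promoter
#' window and in 5'-to-3' window order: two Alu copies (subfamily consensus
#' mutated at `alu_mutation_rate`), a `(TA)n` low-complexity run, and an L1
#' fragment, with inter-element gaps drawn uniformly from
#' `[1, max_gap]`. The PPRE heptamer `TGACCTC` is written into the left arm
#' of the first Alu at consensus offset `ppre_offset` — on the reverse
#' complement strand for every second plant. Genes alternate `+`/`-`
#' strand; repeat annotations are emitted for every placed element.
#'
#' @param config a [sim_config()].
#' @param library named consensus vector from [alu_consensus_library()].
#' @return list with `genome` (named character), `repeats`, `tss`
#'   (data.frames in the io conventions) and `truth` (one row per planted
#'   element plus the PPRE coordinates; the acceptance oracle).
#' @export
simulate_genome <- function(config, library = alu_consensus_library()) {
  stopifnot(inherits(config, "sim_config"), length(library) >= 1)
  set.seed(config$seed)
  L <- config$window_length
  slot <- L + config$intergene_spacing
  margin <- 10L
  need <- margin + config$n_genes * slot + margin
  if (config$chrom_length < need) {
    stop("chrom_length ", config$chrom_length, " too small for ",
         config$n_genes, " genes (needs >= ", need, ")")
  }
  chrom <- "chrS1"
  genome_v <- sample(DNA_BASES, config$chrom_length, replace = TRUE)

  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  strands <- rep(c("+", "-"), length.out = config$n_genes)
  win_start <- margin + (seq_len(config$n_genes) - 1L) * slot  # genome start of window
  tss <- ifelse(strands == "+", win_start + L, win_start - 1L)
  tss_df <- data.frame(gene_id = gene_ids, chrom = chrom, strand = strands,
                       tss = as.integer(tss), stringsAsFactors = FALSE)

  planted <- sort(sample(config$n_genes, config$n_planted_configs))
  rep_rows <- list()
  truth_rows <- list()
  lc_len <- 40L
  l1_len <- 400L
  for (pi in seq_along(planted)) {
    g <- planted[pi]
    subfams <- sample(names(library), 2, replace = length(library) < 2)
    alu_seqs <- vapply(subfams, function(sf) {
      mutate_sequence(library[[sf]], config$alu_mutation_rate)
    }, character(1))
    ppre_rc <- pi %% 2 == 0  # alternate strands across plants
    motif <- if (ppre_rc) revcomp(PPRE_MOTIF) else PPRE_MOTIF
    alu_seqs[1] <- splice_into(alu_seqs[1], motif, config$ppre_offset + 1L)
    lc_seq <- strrep("TA", lc_len / 2)
    l1_seq <- random_dna(l1_len)
    el_seqs <- c(alu_seqs, lc_seq, l1_seq)
    el_names <- c(subfams, "TA_rich_syn", "L1_syn")
    el_class <- c("SINE/Alu", "SINE/Alu", "Low_complexity", "LINE/L1")
    lens <- nchar(el_seqs)
    gaps <- sample(config$max_gap, 3, replace = TRUE)  # uniform on [1, max_gap]
    span <- sum(lens) + sum(gaps)
    if (span > L) {
      stop("planted configuration for ", gene_ids[g], " (span ", span,
           " bp) does not fit the ", L, " bp promoter window")
    }
    s0 <- sample(L - span + 1L, 1) - 1L  # window offset of first element
    offs <- s0 + cumsum(c(0L, lens[-4] + gaps))
    # map window coordinates -> genome; window coord 0 is farthest upstream
    w0 <- win_start[g]
    for (e in 1:4) {
      ws <- offs[e]; we <- offs[e] + lens[e]
      if (strands[g] == "+") {
        gs <- w0 + ws; ge <- w0 + we
        piece <- el_seqs[e]
      } else {
        gs <- w0 + L - we; ge <- w0 + L - ws
        piece <- revcomp(el_seqs[e])
      }
      genome_v[(gs + 1):ge] <- chars(piece)
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        chrom = chrom, start = gs, end = ge, strand = strands[g],
        name = el_names[e], class_family = el_class[e],
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        gene_id = gene_ids[g], element_order = e, name = el_names[e],
        class_family = el_class[e], window_start = ws, window_end = we,
        genomic_start = gs, genomic_end = ge, strand = strands[g],
        stringsAsFactors = FALSE)
    }
    # PPRE coordinates (window offset inside the first Alu)
    pw <- offs[1] + config$ppre_offset
    if (strands[g] == "+") {
      pg <- w0 + pw
      pstrand <- if (ppre_rc) "-" else "+"
    } else {
      pg <- w0 + L - pw - nchar(PPRE_MOTIF)
      pstrand <- if (ppre_rc) "+" else "-"
    }
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      gene_id = gene_ids[g], element_order = 0L, name = "PPRE",
      class_family = "motif", window_start = pw,
      window_end = pw + nchar(PPRE_MOTIF), genomic_start = pg,
      genomic_end = pg + nchar(PPRE_MOTIF), strand = pstrand,
      stringsAsFactors = FALSE)
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else empty_repeats()
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame()
  if (nrow(truth)) {
    truth$ppre_consensus_offset <- config$ppre_offset
    truth$subfamily <- ifelse(truth$class_family == "SINE/Alu", truth$name, NA)
  }
  genome <- stats::setNames(paste(genome_v, collapse = ""), chrom)
  list(genome = genome, repeats = repeats, tss = tss_df, truth = truth,
       planted_genes = gene_ids[planted])
}

#' Simulate a tumor/control two-gene expression pair
#'
#' Per cohort, `(PPARG, DNMT1)` latent values are bivariate normal with the
#' configured population correlation; FPKM-like values are
#' `exp(2 + latent)`, keeping positivity while the correlation structure
#' lives on the latent log scale.
#'
#' @param config a [sim_config()].
#' @param cancer_type cohort label attached to every sample.
#' @return data.frame with columns `sample`, `cancer_type`, `cohort`,
#'   `PPARG`, `DNMT1`.
#' @export
simulate_expression_pair <- function(config, cancer_type = "SYN") {
  e <- config$expression
  stopifnot(e$n_tumor >= 3, e$n_control >= 3)
  set.seed(config$seed)
  one <- function(n, r, cohort) {
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    data.frame(sample = sprintf("%s_%s_%03d", cancer_type, cohort, seq_len(n)),
               cancer_type = cancer_type, cohort = cohort,
               PPARG = exp(2 + z1), DNMT1 = exp(2 + z2),
               stringsAsFactors = FALSE)
  }
  rbind(one(e$n_tumor, e$r_tumor, "tumor"),
        one(e$n_control, e$r_control, "control"))
}

#' Enumerate all missense single-nucleotide changes of a CDS
#'
#' Brute force over every CDS position and its three alternative bases:
#' the mutant codon is translated and kept when the amino acid changes and
#' the change is not a stop gain (missense, not nonsense).
#'
#' @param cds in-frame coding sequence (length divisible by 3, no internal
#'   stop assumed but not enforced).
#' @return data.frame with `pos` (1-based CDS position), `ref`, `alt`,
#'   `aa_ref`, `aa_alt`, `variant` (p.-style label).
#' @export
enumerate_missense <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  v <- chars(cds)
  L <- length(v)
  gc <- Biostrings::GENETIC_CODE
  cm <- matrix(v, nrow = 3)              # codons in columns
  codons <- apply(cm, 2, paste, collapse = "")
  # all 3L candidate substitutions, vectorized
  pos <- rep(seq_len(L), each = 3)
  ref <- v[pos]
  alt <- as.vector(vapply(v, function(b) setdiff(DNA_BASES, b), character(3)))
  ci <- (pos - 1) %/% 3 + 1
  within <- (pos - 1) %% 3 + 1
  b1 <- cm[1, ci]; b2 <- cm[2, ci]; b3 <- cm[3, ci]
  b1[within == 1] <- alt[within == 1]
  b2[within == 2] <- alt[within == 2]
  b3[within == 3] <- alt[within == 3]
  aa_ref <- unname(gc[codons[ci]])
  aa_alt <- unname(gc[paste0(b1, b2, b3)])
  keep <- aa_ref != "*" & aa_alt != "*" & aa_alt != aa_ref
  data.frame(pos = pos[keep], ref = ref[keep], alt = alt[keep],
             aa_ref = aa_ref[keep], aa_alt = aa_alt[keep],
             variant = sprintf("p.%s%d%s", aa_ref[keep], ci[keep],
                               aa_alt[keep]),
             stringsAsFactors = FALSE)
}

#' Simulate observed and null variant-score sets for one gene
#'
#' The null set carries the scores of all possible missense
#' single-nucleotide changes of `cds` (from [enumerate_missense()]); the
#' observed set is `n_observed` draws with replacement, a `band_fraction`
#' of them restricted to `score_band` and the rest drawn from the whole
#' null. When no `score_table` is supplied one is generated with i.i.d.
#' uniform scores on `[0, 100]` under the config seed (the scoring method
#' itself is consumed as input, never computed here).
#'
#' @param config a [sim_config()].
#' @param cds in-frame coding sequence.
#' @param score_table optional data.frame mapping every missense change
#'   (`pos`, `alt`) to a `score` in `[0, 100]`.
#' @return list with `observed` and `null` data.frames (`gene`, `variant`,
#'   `ea_score`) and the `score_table` used.
#' @export
simulate_mutation_sets <- function(config, cds, score_table = NULL) {
  m <- config$mutations
  set.seed(config$seed)
  null <- enumerate_missense(cds)
  if (!nrow(null)) stop("CDS admits no missense change")
  if (is.null(score_table)) {
    score_table <- data.frame(pos = null$pos, alt = null$alt,
                              score = runif(nrow(null), 0, 100))
  }
  key <- paste(null$pos, null$alt)
  idx <- match(key, paste(score_table$pos, score_table$alt))
  if (anyNA(idx)) stop("score_table does not cover every missense change")
  null$ea_score <- score_table$score[idx]
  n_band <- round(m$band_fraction * m$n_observed)
  in_band <- which(null$ea_score >= m$score_band[1] &
                   null$ea_score <= m$score_band[2])
  if (n_band > 0 && !length(in_band)) {
    stop("no null scores inside score_band [", m$score_band[1], ", ",
         m$score_band[2], "]")
  }
  pick <- c(if (n_band > 0) sample(in_band, n_band, replace = TRUE),
            sample(nrow(null), m$n_observed - n_band, replace = TRUE))
  observed <- null[pick, , drop = FALSE]
  rownames(observed) <- NULL
  fmt <- function(df) data.frame(gene = "SYN_GENE", variant = df$variant,
                                 ea_score = df$ea_score,
                                 stringsAsFactors = FALSE)
  list(observed = fmt(observed), null = fmt(null), score_table = score_table)
}

#' Simulate a right-censored survival cohort with expression-linked hazard
#'
#' Expression is drawn log-normal; the cohort is median-split (ties to
#' low); event times are exponential with `hazard_high` for the
#' high-expression group and `hazard_low` otherwise (optionally overridden
#' inside the monosomy 3 stratum); times beyond `censor_time` are censored
#' there. Chromosome 3 class is Bernoulli(`frac_monosomy3`).
#'
#' @param config a [sim_config()].
#' @return data.frame with `case_id`, `time`, `event`, `expression`,
#'   `chr3_class`, `expr_group`.
#' @export
simulate_survival_cohort <- function(config) {
  s <- config$survival
  if (s$n_cases < 4) stop("n_cases must be >= 4")
  set.seed(config$seed)
  n <- s$n_cases
  expr <- exp(rnorm(n, 2, 0.6))
  grp <- median_split(expr)
  chr3 <- ifelse(runif(n) < s$frac_monosomy3, "monosomy3", "disomy3")
  hl <- ifelse(chr3 == "monosomy3", s$hazard_low_m3 %||% s$hazard_low,
               s$hazard_low)
  hh <- ifelse(chr3 == "monosomy3", s$hazard_high_m3 %||% s$hazard_high,
               s$hazard_high)
  haz <- ifelse(grp == "high", hh, hl)
  t_event <- rexp(n, rate = haz)
  event <- as.integer(t_event <= s$censor_time)
  time <- pmin(t_event, s$censor_time)
  data.frame(case_id = sprintf("case%03d", seq_len(n)), time = time,
             event = event, expression = expr, chr3_class = chr3,
             expr_group = grp, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all simulated inputs to a directory
#'
#' Emits exactly the formats the readers consume: `genome.fa`,
#' `repeats.bed` (BED6+1), `tss.bed`, `truth.tsv`, `expression.tsv`,
#' `mutations_observed.tsv` / `mutations_null.tsv`, `survival.csv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param cds CDS used for the mutation sets (default: a seeded random
#'   200-codon CDS).
#' @return invisible named vector of written paths.
#' @export
simulate_all <- function(config, outdir, cds = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  expr <- simulate_expression_pair(config)
  if (is.null(cds)) {
    set.seed(config$seed + 7L)
    cds <- paste0("ATG", random_dna(597))
  }
  muts <- simulate_mutation_sets(config, cds)
  surv <- simulate_survival_cohort(config)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             repeats = file.path(outdir, "repeats.bed"),
             tss = file.path(outdir, "tss.bed"),
             truth = file.path(outdir, "truth.tsv"),
             expression = file.path(outdir, "expression.tsv"),
             mut_obs = file.path(outdir, "mutations_observed.tsv"),
             mut_null = file.path(outdir, "mutations_null.tsv"),
             survival = file.path(outdir, "survival.csv"))
  write_genome_fasta(gen$genome, paths["genome"])
  write_repeat_bed(gen$repeats, paths["repeats"])
  write_tss_bed(gen$tss, paths["tss"])
  write_report_tsv(gen$truth, paths["truth"])
  write_report_tsv(expr, paths["expression"])
  write_report_tsv(muts$observed, paths["mut_obs"])
  write_report_tsv(muts$null, paths["mut_null"])
  utils::write.csv(surv, paths["survival"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
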