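# Orchestration: configuration validation and an end-to-end run that
# chains simulate -> scan -> consensus/assign -> co-expression ->
# score-distribution comparison -> survival, writing every stage's tables
# plus a JSON run manifest. The numbered scripts under analysis/ are thin
# narrative drivers over these functions.

#' Pipeline configuration
#'
#' Flat key-value configuration with defaults; values from a YAML file (if
#' given) override defaults, and `...` overrides both — the same
#' precedence a command line would have.
#'
#' @param path optional YAML file of settings.
#' @param ... individual overrides (e.g. `window_length = 2000`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    outdir = "results/pipeline",
    seed = 1L,
    n_genes = 50L,
    n_planted_configs = 10L,
    alu_mutation_rate = 0,
    chrom_length = 300000L,
    window_length = 4000L,
    scan_window_length = 4000L,
    grammar = "SINE/Alu,SINE/Alu,Low_complexity,LINE/L1",
    max_gap = 500L,
    motif = PPRE_MOTIF,
    identity_threshold = 0.95,
    stages = c("simulate", "scan", "consensus", "coexpr", "ea", "survival")
  )
  if (!is.null(path)) {
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every structural problem at once rather than failing on the
#' first; returns the problems instead of throwing.
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  known_classes <- unique(class_family_map()$class_family)
  terms <- trimws(strsplit(config$grammar, ",")[[1]])
  bad <- setdiff(terms, known_classes)
  if (length(bad)) {
    errs <- c(errs, paste0("unknown grammar class token: ",
                           paste(bad, collapse = ", ")))
  }
  if (config$max_gap < 0) errs <- c(errs, "max_gap must be >= 0")
  if (!nzchar(config$motif)) errs <- c(errs, "motif must be non-empty")
  if (grepl("[^ACGTRYSWKMBDHVN]", toupper(config$motif))) {
    errs <- c(errs, "motif contains non-IUPAC characters")
  }
  if (config$identity_threshold <= 0 || config$identity_threshold > 1) {
    errs <- c(errs, "identity_threshold must be in (0, 1]")
  }
  if (config$window_length < 1) errs <- c(errs, "window_length must be >= 1")
  if (config$seed %% 1 != 0) errs <- c(errs, "seed must be an integer")
  unknown <- setdiff(config$stages,
                     c("simulate", "scan", "consensus", "coexpr", "ea",
                       "survival"))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  errs
}

#' Run the full pipeline
#'
#' Stages run in dependency order under one seed; each writes its outputs
#' under `outdir` and the run ends with a JSON manifest recording the
#' seed, parameters and md5 checksums of every produced file. A stage
#' failure aborts the downstream stages.
#'
#' @param config a [pipeline_config()]; validation errors abort before any
#'   stage runs.
#' @return invisible list with per-stage results and the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  scfg <- sim_config(seed = config$seed, n_genes = config$n_genes,
                     n_planted_configs = config$n_planted_configs,
                     alu_mutation_rate = config$alu_mutation_rate,
                     chrom_length = config$chrom_length,
                     window_length = config$window_length,
                     max_gap = config$max_gap)
  if ("simulate" %in% config$stages) {
    res$simulate <- simulate_all(scfg, outdir)
  }
  if ("scan" %in% config$stages) {
    gen <- simulate_genome(scfg)
    grammar <- configuration_grammar(
      terms = trimws(strsplit(config$grammar, ",")[[1]]),
      max_gap = config$max_gap)
    scan <- genome_scan_similar(gen$genome, gen$tss, gen$repeats, grammar,
                                motif = config$motif,
                                window_length = config$scan_window_length)
    writeLines(scan$genes, file.path(outdir, "genes.txt"))
    write_report_tsv(scan$report, file.path(outdir, "matches.tsv"))
    if (!is.null(scan$hits)) {
      write_hits(scan$hits, file.path(outdir, "hits.bed"), "bed")
      write_hits(scan$hits, file.path(outdir, "hits.tsv"), "tsv")
    }
    res$scan <- scan
  }
  if ("consensus" %in% config$stages) {
    lib <- alu_consensus_library()
    gen <- simulate_genome(scfg)
    # genomic Alu copies in gene orientation, grouped by source subfamily
    copies <- alu_copies_from_truth(gen)
    cons <- lapply(copies, function(seqs) {
      reps <- collapse_redundancy(seqs, config$identity_threshold)$representatives
      if (length(reps) >= 2) call_consensus(build_msa(reps))
      else list(consensus = reps[[1]], pfm = NULL, info_content = NULL)
    })
    cons_fa <- vapply(cons, `[[`, character(1), "consensus")
    write_genome_fasta(cons_fa, file.path(outdir, "subfamily_consensus.fa"))
    if (length(cons_fa) >= 3) {
      nj <- nj_tree(p_distance_matrix(cons_fa))
      writeLines(nj$newick, file.path(outdir, "subfamily_nj.nwk"))
      res$nj <- nj
    }
    assigned <- lapply(names(copies), function(sf) {
      data.frame(copy_subfamily = sf,
                 assigned = vapply(copies[[sf]], function(s) {
                   assign_subfamily(s, lib)$subfamily
                 }, character(1)), stringsAsFactors = FALSE)
    })
    assigned <- do.call(rbind, assigned)
    write_report_tsv(assigned, file.path(outdir, "subfamily_assignment.tsv"))
    res$consensus <- list(consensus = cons_fa, assignment = assigned)
  }
  if ("coexpr" %in% config$stages) {
    expr <- simulate_expression_pair(scfg)
    tab <- correlate_by_cancer(expr)
    write_report_tsv(tab, file.path(outdir, "coexpression.tsv"))
    res$coexpr <- tab
  }
  if ("ea" %in% config$stages) {
    set.seed(scfg$seed + 7L)
    cds <- paste0("ATG", random_dna(597))
    muts <- simulate_mutation_sets(scfg, cds)
    ks <- ks_two_sample(muts$observed$ea_score, muts$null$ea_score)
    write_report_tsv(ks, file.path(outdir, "ea_ks.tsv"))
    res$ea <- ks
  }
  if ("survival" %in% config$stages) {
    cohort <- simulate_survival_cohort(scfg)
    rows <- lapply(c("all", "disomy3", "monosomy3"), function(cf) {
      sg <- subgroup_survival(cohort, cf)
      cbind(data.frame(class_filter = cf), sg$logrank)
    })
    surv_tab <- do.call(rbind, rows)
    write_report_tsv(surv_tab, file.path(outdir, "survival_logrank.tsv"))
    res$survival <- surv_tab
  }
  manifest <- list(
    package = "ppreAlu",
    version = as.character(utils::packageVersion("ppreAlu")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "stages")],
    stages = config$stages,
    files = as.list(tools::md5sum(list.files(outdir, full.names = TRUE,
                                             pattern = "\\.(fa|bed|tsv|csv|txt|nwk)$")))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest_path
  invisible(res)
}

# extract planted Alu copy sequences (gene orientation) grouped by their
# source subfamily, from a simulate_genome() result
alu_copies_from_truth <- function(gen) {
  tr <- gen$truth[gen$truth$class_family == "SINE/Alu", , drop = FALSE]
  if (!nrow(tr)) return(list())
  seqs <- vapply(seq_len(nrow(tr)), function(i) {
    s <- substr(gen$genome[[1]], tr$genomic_start[i] + 1, tr$genomic_end[i])
    if (tr$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
  split(seqs, tr$subfamily)
}
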