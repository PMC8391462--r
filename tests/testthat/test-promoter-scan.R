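test_that("promoter windows obey the coordinate convention on both strands", {
  set.seed(13)
  genome <- c(A = rand_dna(8000), B = rand_dna(200))
  tss <- data.frame(gene_id = c("gp", "gm"), chrom = c("A", "B"),
                    strand = c("+", "-"), tss = c(4000L, 99L),
                    stringsAsFactors = FALSE)
  w <- extract_promoter_windows(genome, tss[1, ], 4000L)
  expect_equal(c(w$start[1], w$end[1]), c(0L, 4000L))
  expect_identical(w$seq[1], substr(genome[["A"]], 1, 4000))

  w2 <- extract_promoter_windows(genome, tss[2, ], 10L)
  expect_equal(c(w2$start, w2$end), c(100L, 110L))
  # minus-strand window sequence is the reverse complement of the slice
  expect_identical(w2$seq, rc_oracle(substr(genome[["B"]], 101, 110)))

  # clipping at the contig edge warns and shortens the window
  tss3 <- data.frame(gene_id = "gc", chrom = "A", strand = "+", tss = 5L)
  expect_warning(w3 <- extract_promoter_windows(genome, tss3, 4000L),
                 "clipped")
  expect_equal(c(w3$start, w3$end), c(0L, 5L))
  expect_error(extract_promoter_windows(genome, data.frame(
    gene_id = "gx", chrom = "A", strand = "+", tss = 9999L), 10L),
    "beyond contig end")
})

make_window <- function(len = 2000L) {
  data.frame(gene_id = "g", chrom = "c", start = 0L, end = len,
             strand = "+", window_length = len,
             seq = strrep("A", len), stringsAsFactors = FALSE)
}

rep_row <- function(start, end, class, name = class, strand = "+") {
  data.frame(chrom = "c", start = start, end = end, strand = strand,
             name = name, class_family = class, stringsAsFactors = FALSE)
}

test_that("the worked grammar example yields one match with gaps 50/50/50", {
  reps <- rbind(rep_row(0L, 300L, "SINE/Alu", "Alu1"),
                rep_row(350L, 650L, "SINE/Alu", "Alu2"),
                rep_row(700L, 750L, "Low_complexity"),
                rep_row(800L, 1200L, "LINE/L1"))
  m <- match_configuration(make_window(), reps, configuration_grammar())
  expect_length(m, 1)
  expect_equal(m[[1]]$gaps, c(50L, 50L, 50L))
  expect_identical(m[[1]]$elements$name[1:2], c("Alu1", "Alu2"))

  expect_length(match_configuration(make_window(), empty_repeats_df(),
                                    configuration_grammar()), 0)

  # three Alus admit exactly two alternative assignments (1+2 or 2+3):
  # the 1->3 gap of 551 bp exceeds max_gap, the others fit
  reps3 <- rbind(rep_row(0L, 300L, "SINE/Alu"),
                 rep_row(350L, 650L, "SINE/Alu"),
                 rep_row(851L, 1151L, "SINE/Alu"),
                 rep_row(1000L, 1050L, "Low_complexity"),
                 rep_row(1200L, 1600L, "LINE/L1"))
  m3 <- match_configuration(make_window(), reps3, configuration_grammar())
  expect_length(m3, 2)
  wr3 <- ppreAlu:::window_repeats(make_window(), reps3)
  expect_length(brute_matches(wr3, configuration_grammar()$terms, 500L), 2)

  # gaps above max_gap never match
  far <- rbind(rep_row(0L, 300L, "SINE/Alu"),
               rep_row(901L, 1201L, "SINE/Alu"),
               rep_row(1300L, 1350L, "Low_complexity"),
               rep_row(1400L, 1800L, "LINE/L1"))
  expect_length(match_configuration(make_window(), far,
                                    configuration_grammar(max_gap = 500L)), 0)
})

test_that("grammar matching equals brute-force subsequence enumeration", {
  set.seed(31)
  grammar <- configuration_grammar()
  classes <- c("SINE/Alu", "SINE/Alu", "LINE/L1", "Low_complexity",
               "Simple_repeat")
  for (rep_i in 1:60) {
    n <- sample(0:12, 1)
    if (n == 0) {
      reps <- empty_repeats_df()
    } else {
      starts <- sort(sample(0:1800, n))
      reps <- do.call(rbind, lapply(seq_len(n), function(i) {
        rep_row(starts[i], starts[i] + sample(50:400, 1),
                sample(classes, 1), strand = sample(c("+", "-"), 1))
      }))
    }
    w <- make_window()
    got <- match_configuration(w, reps, grammar)
    wr <- ppreAlu:::window_repeats(w, reps)
    want <- brute_matches(wr, grammar$terms, grammar$max_gap)
    expect_length(got, length(want))
    if (length(got)) {
      got_keys <- sort(vapply(got, function(m) {
        paste(m$elements$wstart, collapse = ",")
      }, character(1)))
      want_keys <- sort(vapply(want, function(idx) {
        paste(wr$wstart[idx], collapse = ",")
      }, character(1)))
      expect_identical(got_keys, want_keys)
    }
  }
})

test_that("same-strand orientation policy filters mixed-strand runs", {
  reps <- rbind(rep_row(0L, 300L, "SINE/Alu", strand = "+"),
                rep_row(350L, 650L, "SINE/Alu", strand = "-"),
                rep_row(700L, 750L, "Low_complexity", strand = "+"),
                rep_row(800L, 1200L, "LINE/L1", strand = "+"))
  any_pol <- configuration_grammar()
  same_pol <- configuration_grammar(orientation_policy = "same_strand")
  expect_length(match_configuration(make_window(), reps, any_pol), 1)
  expect_length(match_configuration(make_window(), reps, same_pol), 0)
})

test_that("motif scanning finds exact and reverse-complement hits only", {
  s <- paste0(strrep("A", 20), "TGACCTC", strrep("A", 20))
  h <- scan_ppre(s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$offset, 20L)
  expect_equal(h$strand, "+")

  h2 <- scan_ppre("GAGGTCA")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")

  expect_equal(nrow(scan_ppre(strrep("N", 100))), 0L)
  expect_error(scan_ppre("ACGT", ""), "empty motif")

  # overlapping occurrences are all reported
  h3 <- scan_ppre("AAAA", motif = "AA", search_both_strands = FALSE)
  expect_equal(h3$offset, 0:2)

  # IUPAC degeneracy: DR1-style motif with one degenerate position
  h4 <- scan_ppre("TGACCTT", motif = "TGACCTY", search_both_strands = FALSE)
  expect_equal(nrow(h4), 1L)
  # sequence N never matches, even against a degenerate motif position
  expect_equal(nrow(scan_ppre("TGACCTN", motif = "TGACCTY",
                              search_both_strands = FALSE)), 0L)
})

test_that("motif scanning equals the naive sliding-window oracle", {
  set.seed(17)
  for (k in 1:25) {
    s <- rand_dna(10000)
    got <- scan_ppre(s)
    want <- naive_scan(s, "TGACCTC")
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("hits inside planted Alus map near the planted consensus offset", {
  gen <- small_sim()
  scan <- genome_scan_similar(gen$genome, gen$tss, gen$repeats,
                              window_length = 4000L)
  h <- scan$hits[!is.na(scan$hits$alu_name), ]
  ppre <- gen$truth[gen$truth$name == "PPRE", ]
  expect_equal(nrow(h), nrow(ppre))
  # at mutation rate 0 the alignment maps the hit to the planted offset up
  # to +-1 (a motif splice can make a gapped alignment strictly optimal)
  expect_true(all(abs(h$consensus_offset - 62) <= 1))
  expect_true(all(h$arm == "left"))
  expect_true(all(h$adjacent_box == "B-box"))
  # genomic coordinates and strands equal the generator's planted truth
  key <- function(d, s) paste(d$genomic_start, s, sep = "/")
  expect_setequal(key(h, h$genomic_strand), key(ppre, ppre$strand))

  # intergenic hits stay unannotated
  w <- extract_promoter_windows(gen$genome, gen$tss[1, , drop = FALSE], 4000L)
  h0 <- annotate_alu_context(scan_ppre(w$seq), w, empty_repeats_df())
  if (nrow(h0)) {
    expect_true(all(h0$arm == "none"))
    expect_true(all(h0$adjacent_box == "none"))
  }
})

test_that("alignment mapping tolerates 10% Alu divergence", {
  gen <- small_sim(seed = 8, alu_mutation_rate = 0.10)
  scan <- genome_scan_similar(gen$genome, gen$tss, gen$repeats,
                              window_length = 4000L)
  # planted hits only: mutation can create chance motifs at other offsets
  ppre <- gen$truth[gen$truth$name == "PPRE", ]
  h <- merge(scan$hits, ppre[, c("gene_id", "genomic_start")],
             by = c("gene_id", "genomic_start"))
  expect_equal(nrow(h), nrow(ppre))
  expect_true(all(abs(h$consensus_offset - 62) <= 5))
  # recovery stays complete at this divergence (the motif is never mutated)
  expect_identical(scan$genes, gen$planted_genes)
})

test_that("genome scan returns exactly the planted genes", {
  gen <- small_sim(seed = 2)
  scan <- genome_scan_similar(gen$genome, gen$tss, gen$repeats,
                              window_length = 4000L)
  expect_identical(scan$genes, gen$planted_genes)
  expect_equal(sum(scan$report$qualifies), 4L)

  none <- small_sim(seed = 2, n_planted_configs = 0L)
  scan0 <- genome_scan_similar(none$genome, none$tss, none$repeats,
                               window_length = 4000L)
  expect_length(scan0$genes, 0)
})

test_that("reverse-complementing the genome preserves hits genomically", {
  gen <- small_sim(seed = 4)
  clen <- nchar(gen$genome[[1]])
  scan1 <- genome_scan_similar(gen$genome, gen$tss, gen$repeats,
                               window_length = 4000L)
  # mirror the whole scene: flip sequence, TSS strands and repeat strands
  genome2 <- stats::setNames(revcomp(gen$genome[[1]]), names(gen$genome))
  tss2 <- gen$tss
  tss2$tss <- clen - 1L - gen$tss$tss
  tss2$strand <- ifelse(gen$tss$strand == "+", "-", "+")
  reps2 <- gen$repeats
  reps2$start <- clen - gen$repeats$end
  reps2$end <- clen - gen$repeats$start
  reps2$strand <- ifelse(gen$repeats$strand == "+", "-", "+")
  scan2 <- genome_scan_similar(genome2, tss2, reps2, window_length = 4000L)
  expect_identical(scan2$genes, scan1$genes)
  # hit positions map through the mirror: start' = clen - end
  key1 <- sort(paste(clen - scan1$hits$genomic_end,
                     ifelse(scan1$hits$genomic_strand == "+", "-", "+")))
  key2 <- sort(paste(scan2$hits$genomic_start, scan2$hits$genomic_strand))
  expect_identical(key2, key1)
})
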