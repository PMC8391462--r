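# Core discovery computation: promoter window extraction, ordered
# repeat-configuration grammar matching, PPRE motif scanning, and
# annotation of each hit's position inside the Alu dimeric structure.

#' Default repeat-configuration grammar
#'
#' The ordered grammar Alu-Alu-Low_complexity-LINE/L1 with a configurable
#' maximum gap between consecutive elements and an orientation policy.
#'
#' @param terms ordered class/family terms.
#' @param max_gap largest allowed gap (bp) between consecutive matched
#'   elements; gaps may be negative (overlapping elements) and are only
#'   bounded from above. "Proximal" is operationalised as 500 bp.
#' @param orientation_policy `"any"` or `"same_strand"`.
#' @return list of class `config_grammar`.
#' @export
configuration_grammar <- function(terms = c("SINE/Alu", "SINE/Alu",
                                            "Low_complexity", "LINE/L1"),
                                  max_gap = 500L,
                                  orientation_policy = c("any", "same_strand")) {
  orientation_policy <- match.arg(orientation_policy)
  stopifnot(length(terms) >= 1, max_gap >= 0)
  structure(list(terms = terms, max_gap = as.integer(max_gap),
                 orientation_policy = orientation_policy),
            class = "config_grammar")
}

#' Extract promoter windows upstream of each TSS
#'
#' A `+` strand gene with TSS `t` gets the genomic interval `[t - L, t)`;
#' a `-` strand gene gets `[t + 1, t + 1 + L)` with the sequence
#' reverse-complemented, so window coordinate 0 is always the position
#' farthest upstream and the sequence reads 5' to 3' of the gene. Windows
#' are clipped at contig bounds with a warning.
#'
#' @param genome named character vector of contig sequences.
#' @param tss data.frame from [read_tss_bed()].
#' @param window_length window length in bp (4000 and 2000 are the two
#'   standard choices).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (genomic,
#'   0-based half-open), `strand`, `window_length`, `seq`.
#' @export
extract_promoter_windows <- function(genome, tss, window_length = 4000L) {
  miss <- setdiff(tss$chrom, names(genome))
  if (length(miss)) stop("TSS on unknown contig(s): ", paste(miss, collapse = ", "))
  L <- as.integer(window_length)
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    chrom <- tss$chrom[i]
    clen <- nchar(genome[[chrom]])
    t <- tss$tss[i]
    if (t >= clen) stop("TSS of ", tss$gene_id[i], " beyond contig end")
    if (tss$strand[i] == "+") {
      s <- t - L; e <- t
    } else {
      s <- t + 1L; e <- t + 1L + L
    }
    cs <- max(0L, s); ce <- min(clen, e)
    if (cs != s || ce != e) {
      warning("promoter window of ", tss$gene_id[i], " clipped to [",
              cs, ", ", ce, ")")
    }
    sq <- substr(genome[[chrom]], cs + 1L, ce)
    if (tss$strand[i] == "-") sq <- revcomp(sq)
    data.frame(gene_id = tss$gene_id[i], chrom = chrom, start = cs, end = ce,
               strand = tss$strand[i], window_length = L, seq = sq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# map repeats overlapping a window into window coordinates (5'->3' of the
# gene); coordinates may extend past the window edges
window_repeats <- function(window, repeats) {
  r <- repeats[repeats$chrom == window$chrom &
                 repeats$start < window$end & repeats$end > window$start, ,
               drop = FALSE]
  if (!nrow(r)) {
    r$wstart <- integer(0); r$wend <- integer(0); r$wstrand <- character(0)
    return(r)
  }
  if (window$strand == "+") {
    r$wstart <- r$start - window$start
    r$wend <- r$end - window$start
    r$wstrand <- r$strand
  } else {
    r$wstart <- window$end - r$end
    r$wend <- window$end - r$start
    r$wstrand <- ifelse(r$strand == "+", "-", "+")
  }
  r <- r[order(r$wstart, r$wend, r$name), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Match the repeat-configuration grammar inside one promoter window
#'
#' Returns every ordered assignment of window-overlapping repeats to the
#' grammar terms such that element classes match term for term, window
#' start coordinates strictly increase, each consecutive gap
#' (`next start - previous end`) is at most `max_gap`, and the orientation
#' policy holds. Overlapping alternative assignments are all reported, in
#' deterministic (lexicographic-by-index) order.
#'
#' @param window one row of [extract_promoter_windows()].
#' @param repeats repeat annotation data.frame (genomic coordinates).
#' @param grammar a [configuration_grammar()].
#' @return list of matches; each has `gene_id`, `elements` (the matched
#'   repeat rows with window coordinates, grammar order) and `gaps`.
#' @export
match_configuration <- function(window, repeats, grammar) {
  wr <- window_repeats(window, repeats)
  k <- length(grammar$terms)
  out <- list()
  if (nrow(wr) < k) return(out)
  dfs <- function(term_i, prev_idx, picked) {
    if (term_i > k) {
      el <- wr[picked, , drop = FALSE]
      out[[length(out) + 1]] <<- list(
        gene_id = window$gene_id, elements = el,
        gaps = if (k > 1) el$wstart[-1] - el$wend[-k] else integer(0))
      return()
    }
    cand <- which(wr$class_family == grammar$terms[term_i])
    for (j in cand) {
      if (length(picked)) {
        if (wr$wstart[j] <= wr$wstart[prev_idx]) next
        if (wr$wstart[j] - wr$wend[prev_idx] > grammar$max_gap) next
        if (grammar$orientation_policy == "same_strand" &&
            wr$wstrand[j] != wr$wstrand[picked[1]]) next
      }
      dfs(term_i + 1, j, c(picked, j))
    }
  }
  dfs(1, 0L, integer(0))
  out
}

# IUPAC code -> character class over ACGT (sequence N never matches)
iupac_class <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

iupac_regex <- function(motif) {
  v <- chars(toupper(motif))
  bad <- !(v %in% names(iupac_class))
  if (any(bad)) stop("motif contains non-IUPAC character: ", v[bad][1])
  paste(iupac_class[v], collapse = "")
}

#' Scan a sequence for a PPRE motif on both strands
#'
#' Reports every (possibly overlapping) occurrence of `motif` and, when
#' `search_both_strands`, of its reverse complement, with the strand
#' recorded relative to the scanned sequence. IUPAC degeneracy is
#' supported in the motif; an `N` in the sequence never matches.
#'
#' @param seq DNA string (a promoter window, 5'->3' of the gene).
#' @param motif IUPAC motif; default the PPRE heptamer `TGACCTC`.
#' @param search_both_strands also scan for the reverse complement
#'   (`GAGGTCA` for the default), recorded as strand `-`.
#' @return data.frame with `offset` (0-based start in `seq`), `strand`
#'   (`+`/`-` relative to `seq`), `text` (matched text as it appears in
#'   `seq`), ordered by offset then strand.
#' @export
scan_ppre <- function(seq, motif = PPRE_MOTIF, search_both_strands = TRUE) {
  if (!nzchar(motif)) stop("empty motif")
  hits <- list()
  scan1 <- function(pattern, strand) {
    m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(offset = as.integer(m) - 1L, strand = strand,
               text = substring(seq, m, m + nchar(motif) - 1L),
               stringsAsFactors = FALSE)
  }
  hits[[1]] <- scan1(iupac_regex(motif), "+")
  if (search_both_strands) {
    hits[[2]] <- scan1(iupac_regex(revcomp(motif)), "-")
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default Alu internal-promoter coordinates on the consensus
#'
#' A-box `[6, 32)`, B-box `[72, 101)`, left arm `[0, 132)` and an A-rich
#' linker up to 170, all 0-based half-open on the subfamily consensus;
#' configurable per subfamily.
#'
#' @param a_box,b_box length-2 integer intervals.
#' @param left_arm_end,linker_end arm boundaries.
#' @param adjacency_bp a hit is "adjacent" to a box when its consensus
#'   interval lies within this many bp of the box interval.
#' @return list of class `alu_box_coords`.
#' @export
alu_box_coords <- function(a_box = c(6L, 32L), b_box = c(72L, 101L),
                           left_arm_end = 132L, linker_end = 170L,
                           adjacency_bp = 10L) {
  structure(list(a_box = a_box, b_box = b_box, left_arm_end = left_arm_end,
                 linker_end = linker_end, adjacency_bp = adjacency_bp),
            class = "alu_box_coords")
}

# gap (bp) between two 0-based half-open intervals; 0 when they overlap
interval_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

#' Annotate PPRE hits with their position inside the Alu structure
#'
#' For each hit that starts inside an annotated `SINE/Alu` feature of the
#' window, the genomic Alu copy is globally aligned to its subfamily
#' consensus (falling back to the first library entry when the subfamily
#' is not in the library) and the hit start is mapped through the
#' alignment to a consensus offset. The arm is `left` / `linker` / `right`
#' per the box coordinates, and the hit is flagged adjacent to the B-box
#' (or A-box) when its consensus interval lies within `adjacency_bp` of
#' that box. Hits outside any Alu get `arm = "none"`.
#'
#' @param hits data.frame from [scan_ppre()] (window offsets).
#' @param window one row of [extract_promoter_windows()].
#' @param repeats repeat annotations (genomic coordinates).
#' @param consensus_library named consensus vector.
#' @param box_coords an [alu_box_coords()].
#' @return `hits` with added columns `alu_name`, `alu_subfamily`,
#'   `consensus_offset`, `arm`, `adjacent_box`.
#' @export
annotate_alu_context <- function(hits, window, repeats,
                                 consensus_library = alu_consensus_library(),
                                 box_coords = alu_box_coords()) {
  n <- nrow(hits)
  hits$alu_name <- rep(NA_character_, n)
  hits$alu_subfamily <- rep(NA_character_, n)
  hits$consensus_offset <- rep(NA_integer_, n)
  hits$arm <- rep("none", n)
  hits$adjacent_box <- rep("none", n)
  if (!n) return(hits)
  wr <- window_repeats(window, repeats)
  alus <- wr[wr$class_family == "SINE/Alu", , drop = FALSE]
  if (!nrow(alus)) return(hits)
  mlen <- nchar(hits$text[1])
  aln_cache <- list()
  for (h in seq_len(n)) {
    off <- hits$offset[h]
    inside <- which(alus$wstart <= off & off < alus$wend)
    if (!length(inside)) next
    a <- inside[1]
    key <- as.character(a)
    if (is.null(aln_cache[[key]])) {
      # Alu copy sequence in gene orientation, clipped to the window
      cs <- max(alus$wstart[a], 0L)
      ce <- min(alus$wend[a], nchar(window$seq))
      copy <- substr(window$seq, cs + 1L, ce)
      if (alus$wstrand[a] == "-") copy <- revcomp(copy)
      sf <- alus$name[a]
      cons <- if (sf %in% names(consensus_library)) {
        consensus_library[[sf]]
      } else {
        consensus_library[[1]]
      }
      aln_cache[[key]] <- list(aln = align_pair(cons, copy), clip = cs,
                               sf = if (sf %in% names(consensus_library)) sf
                                    else names(consensus_library)[1])
    }
    entry <- aln_cache[[key]]
    copy_pos <- if (alus$wstrand[a] == "-") {
      # position of the hit start on the consensus-oriented copy
      (min(alus$wend[a], nchar(window$seq)) - 1L) - (off + mlen - 1L)
    } else {
      off - entry$clip
    }
    co <- map_through_alignment(entry$aln, copy_pos)
    hits$alu_name[h] <- alus$name[a]
    hits$alu_subfamily[h] <- entry$sf
    hits$consensus_offset[h] <- co
    hits$arm[h] <- if (co < box_coords$left_arm_end) "left"
      else if (co < box_coords$linker_end) "linker" else "right"
    dB <- interval_gap(co, co + mlen, box_coords$b_box[1], box_coords$b_box[2])
    dA <- interval_gap(co, co + mlen, box_coords$a_box[1], box_coords$a_box[2])
    hits$adjacent_box[h] <- if (dB <= box_coords$adjacency_bp) "B-box"
      else if (dA <= box_coords$adjacency_bp) "A-box" else "none"
  }
  hits
}

# map a 0-based position on the second (copy) sequence of a pairwise
# alignment onto the first (consensus) sequence
map_through_alignment <- function(aln, copy_pos) {
  ca <- chars(aln$aligned_a)
  cb <- chars(aln$aligned_b)
  bcount <- cumsum(cb != "-")
  col <- which(bcount == copy_pos + 1 & cb != "-")[1]
  if (is.na(col)) return(NA_integer_)
  acount <- cumsum(ca != "-")
  # consensus offset of this column (position of the last consensus char
  # at or before it)
  max(0L, acount[col] - if (ca[col] != "-") 1L else 0L)
}

#' Genome-wide scan for genes with a similar PPRE-Alu configuration
#'
#' Runs extract -> match -> scan -> annotate for every gene. A gene
#' qualifies when it has at least one configuration match and at least one
#' PPRE hit starting inside an Alu element of such a match.
#'
#' @param genome named contig vector.
#' @param tss TSS data.frame.
#' @param repeats repeat annotations.
#' @param grammar a [configuration_grammar()].
#' @param motif IUPAC motif.
#' @param window_length promoter window length (2000 for the narrowed
#'   genome-wide scan; 4000 for the wide discovery window).
#' @param consensus_library,box_coords passed to [annotate_alu_context()].
#' @return list with `genes` (qualifying gene ids, sorted), `report` (one
#'   row per gene: match/hit counts and qualification) and `hits` (all
#'   annotated hits with genomic coordinates).
#' @export
genome_scan_similar <- function(genome, tss, repeats,
                                grammar = configuration_grammar(),
                                motif = PPRE_MOTIF,
                                window_length = 2000L,
                                consensus_library = alu_consensus_library(),
                                box_coords = alu_box_coords()) {
  windows <- extract_promoter_windows(genome, tss, window_length)
  report <- list()
  all_hits <- list()
  genes <- character(0)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, , drop = FALSE]
    matches <- match_configuration(w, repeats, grammar)
    hits <- scan_ppre(w$seq, motif)
    hits <- annotate_alu_context(hits, w, repeats, consensus_library,
                                 box_coords)
    # does some hit start inside an Alu element of some match?
    in_alu_match <- FALSE
    if (nrow(hits) && length(matches)) {
      for (m in matches) {
        alus <- m$elements[m$elements$class_family == "SINE/Alu", ,
                           drop = FALSE]
        for (a in seq_len(nrow(alus))) {
          if (any(hits$offset >= alus$wstart[a] &
                  hits$offset < alus$wend[a])) {
            in_alu_match <- TRUE
          }
        }
      }
    }
    qualifies <- length(matches) >= 1 && in_alu_match
    if (qualifies) genes <- c(genes, w$gene_id)
    report[[i]] <- data.frame(
      gene_id = w$gene_id, n_matches = length(matches),
      n_hits = nrow(hits), n_hits_in_alu = sum(!is.na(hits$alu_name)),
      qualifies = qualifies, stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hits$gene_id <- w$gene_id
      hits$chrom <- w$chrom
      mlen <- nchar(motif)
      if (w$strand == "+") {
        hits$genomic_start <- w$start + hits$offset
        hits$genomic_strand <- hits$strand
      } else {
        hits$genomic_start <- w$end - hits$offset - mlen
        hits$genomic_strand <- ifelse(hits$strand == "+", "-", "+")
      }
      hits$genomic_end <- hits$genomic_start + mlen
      all_hits[[length(all_hits) + 1]] <- hits
    }
  }
  hits_df <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  list(genes = sort(unique(genes)), report = do.call(rbind, report),
       hits = hits_df)
}
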