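# Readers/writers for the formats the pipeline touches.
# One convention everywhere: coordinates are 0-based half-open, BED-style.
# RepeatMasker .out (1-based inclusive) is converted at parse time.

#' Read a genome FASTA into named uppercase strings
#'
#' Wrapped lines are joined and lowercase bases are uppercased. The alphabet
#' is restricted to `{A,C,G,T,N}`; anything else is a format error naming the
#' offending record.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(character(0))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character in FASTA record '", names(seqs)[bad][1],
         "': alphabet is restricted to A,C,G,T,N")
  }
  seqs
}

#' Write named DNA strings to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# controlled vocabulary for repeat class/family names, shipped as config
class_family_map <- function() {
  path <- system.file("extdata", "class_family_map.tsv", package = "ppreAlu")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Normalize repeat class/family labels
#'
#' Maps dialect variants (e.g. `"Alu"`, `"SINE/Alu"`) onto the controlled
#' vocabulary used internally (`SINE/Alu`, `LINE/L1`, `Low_complexity`,
#' `Simple_repeat`, ...). Unknown labels pass through unchanged with a
#' warning rather than failing: repeat catalogues routinely contain classes
#' the grammar never references.
#'
#' @param x character vector of class/family labels.
#' @return character vector of normalized labels.
#' @export
normalize_class_family <- function(x) {
  map <- class_family_map()
  idx <- match(x, map$alias)
  out <- ifelse(is.na(idx), x, map$class_family[idx])
  unknown <- unique(x[is.na(idx) & !(x %in% map$class_family)])
  if (length(unknown)) {
    warning("unknown repeat class/family label(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' Read repeat annotations (RepeatMasker .out or BED6+1)
#'
#' Both dialects are normalized to 0-based half-open coordinates and a
#' controlled class/family vocabulary. For `rmsk_out` the usual two header
#' lines (plus optional blank line) are skipped and query coordinates
#' (1-based inclusive) are shifted; a RepeatMasker strand of `C` becomes
#' `-`. The BED dialect expects BED6 plus the class/family in column 7.
#' Records with `end <= start` are dropped with a summary warning.
#'
#' @param path annotation file.
#' @param dialect `"rmsk_out"` or `"bed"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `class_family` (0-based half-open).
#' @export
read_repeat_annotations <- function(path, dialect = c("bed", "rmsk_out")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "rmsk_out") {
    lines <- readLines(path)
    # skip the 2-line header and any blank separator lines
    body <- lines[-seq_len(min(2L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) return(empty_repeats())
    fields <- strsplit(trimws(body), "\\s+")
    n <- lengths(fields)
    if (any(n < 11)) stop("malformed rmsk .out row (needs >= 11 fields) at data line ",
                          which(n < 11)[1])
    df <- data.frame(
      chrom = vapply(fields, `[`, character(1), 5),
      start = as.integer(vapply(fields, `[`, character(1), 6)) - 1L,
      end = as.integer(vapply(fields, `[`, character(1), 7)),
      strand = ifelse(vapply(fields, `[`, character(1), 9) == "C", "-", "+"),
      name = vapply(fields, `[`, character(1), 10),
      class_family = vapply(fields, `[`, character(1), 11),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("chrom", "start", "end", "name", "score",
                                   "strand", "class_family"),
                     colClasses = c("character", "integer", "integer",
                                    "character", "character", "character",
                                    "character"))
    df <- df[, c("chrom", "start", "end", "strand", "name", "class_family")]
  }
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sum(bad), " record(s) with end <= start dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df$class_family <- normalize_class_family(df$class_family)
  rownames(df) <- NULL
  df
}

empty_repeats <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), name = character(0),
             class_family = character(0), stringsAsFactors = FALSE)
}

#' Write repeat annotations as BED6+1
#'
#' @param repeats data.frame as returned by [read_repeat_annotations()].
#' @param path output path.
#' @export
write_repeat_bed <- function(repeats, path) {
  out <- data.frame(repeats$chrom, repeats$start, repeats$end, repeats$name,
                    0L, repeats$strand, repeats$class_family)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TSS records from BED6
#'
#' One record per gene: the TSS is the `start` field (a single-base BED
#' interval, `end = start + 1`); the strand column is authoritative.
#' Gene identifiers must be unique within a file.
#'
#' @param path BED6 file.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based).
#' @export
read_tss_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"))
  if (anyDuplicated(df$name)) {
    stop("duplicate gene_id in TSS file: ",
         df$name[duplicated(df$name)][1])
  }
  if (any(df$start < 0)) stop("negative TSS coordinate")
  if (!all(df$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  data.frame(gene_id = df$name, chrom = df$chrom, strand = df$strand,
             tss = df$start, stringsAsFactors = FALSE)
}

#' Write TSS records as BED6
#'
#' @param tss data.frame as returned by [read_tss_bed()].
#' @param path output path.
#' @export
write_tss_bed <- function(tss, path) {
  out <- data.frame(tss$chrom, tss$tss, tss$tss + 1L, tss$gene_id, 0L,
                    tss$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write PPRE hits to BED6 or a context TSV
#'
#' BED6 output carries genomic coordinates (0-based half-open) with the hit
#' strand relative to the reference; the TSV keeps every Alu-context column
#' (window offset, containing Alu, consensus offset, arm, adjacent box).
#' Rows are ordered deterministically by (chrom, start, gene_id).
#'
#' @param hits data.frame of annotated hits (see [genome_scan_similar()]).
#' @param path output path.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  ord <- order(hits$chrom, hits$genomic_start, hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  if (format == "bed") {
    out <- data.frame(hits$chrom, hits$genomic_start, hits$genomic_end,
                      paste0(hits$gene_id, ":", hits$text),
                      0L, hits$genomic_strand)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write_report_tsv(hits, path)
  }
  invisible(path)
}

#' Write a report table as TSV (UTF-8, header row)
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a report table written by [write_report_tsv()]
#'
#' @param path TSV path.
#' @return data.frame; `read_report_tsv(write_report_tsv(x)) == x` for
#'   tables of atomic columns.
#' @export
read_report_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8", check.names = FALSE)
}
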