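# Standard-format I/O: FASTA/FASTQ, PAF and BLAST tabular alignments, BED6.

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path (gzip-compressed files are handled transparently).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  readDNAStringSet(path, format = format)
}

#' Write sequences as FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path, format = "fasta",
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write reads as FASTQ with constant placeholder qualities
#'
#' Simulated reads carry no meaningful per-base quality; a constant Sanger
#' quality character is emitted. Records are written through a plain text
#' connection, which (unlike the fixed line buffer of the XStringSet FASTQ
#' writer) handles reads of any length.
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path; `.gz` triggers compression.
#' @param quality single quality character (default `"I"`).
#' @export
writeFastq <- function(x, path, quality = "I") {
  seqs <- as.character(x)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("read", seq_along(seqs))
  quals <- strrep(quality, nchar(seqs))
  lines <- as.vector(rbind(paste0("@", names(seqs)), seqs, "+", quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write genomic regions as BED6 (0-based half-open)
#'
#' @param regions data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @export
writeRegionsBed <- function(regions, path) {
  n <- nrow(regions)
  bed <- data.frame(
    chrom = regions$chromosome,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(regions)) regions$name else
      paste0("region", seq_len(n)),
    score = if ("score" %in% names(regions)) regions$score else 0L,
    strand = if ("strand" %in% names(regions)) regions$strand else ".",
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Parse precomputed alignments into the internal hit frame
#'
#' Ingests minimap2-style PAF or BLAST tabular (outfmt 6: `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`)
#' alignments, normalising all coordinates to the internal 0-based half-open
#' frame with read intervals on the forward read. BLAST coordinates are
#' 1-based inclusive and minus-strand hits have reversed subject
#' coordinates; both conventions are converted.
#'
#' @param path alignment file.
#' @param dialect `"paf"` or `"blast6"`.
#' @param targetKind label for the `target_kind` column.
#' @return a hit data.frame.
#' @export
parseAlignments <- function(path, dialect = c("paf", "blast6"),
                            targetKind = "genome") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyHitFrame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  minCols <- if (dialect == "paf") 12L else 12L
  bad <- which(vapply(fields, length, integer(1)) < minCols)
  if (length(bad))
    stop("malformed ", dialect, " line ", bad[1], " in ", path)
  if (dialect == "paf") {
    num <- function(k) as.numeric(vapply(fields, `[[`, character(1), k))
    chrv <- function(k) vapply(fields, `[[`, character(1), k)
    nmatch <- num(10); alen <- num(11)
    out <- data.frame(
      read_id = chrv(1), read_length = as.integer(num(2)),
      read_start = as.integer(num(3)), read_end = as.integer(num(4)),
      target_id = chrv(6),
      target_start = as.integer(num(8)), target_end = as.integer(num(9)),
      strand = chrv(5), identity = ifelse(alen > 0, nmatch / alen, 0),
      n_seeds = NA_integer_, target_kind = targetKind,
      stringsAsFactors = FALSE)
    if (any(is.na(out$read_start)) || any(!out$strand %in% c("+", "-")))
      stop("malformed paf line ",
           which(is.na(out$read_start) | !out$strand %in% c("+", "-"))[1],
           " in ", path)
  } else {
    num <- function(k) as.numeric(vapply(fields, `[[`, character(1), k))
    chrv <- function(k) vapply(fields, `[[`, character(1), k)
    qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
    if (any(is.na(c(qs, qe, ss, se))))
      stop("malformed blast6 line ", which(is.na(qs + qe + ss + se))[1],
           " in ", path)
    minus <- ss > se
    ts <- ifelse(minus, se, ss) - 1
    te <- ifelse(minus, ss, se)
    out <- data.frame(
      read_id = chrv(1), read_length = NA_integer_,
      read_start = as.integer(qs - 1), read_end = as.integer(qe),
      target_id = chrv(2),
      target_start = as.integer(ts), target_end = as.integer(te),
      strand = ifelse(minus, "-", "+"), identity = num(3) / 100,
      n_seeds = NA_integer_, target_kind = targetKind,
      stringsAsFactors = FALSE)
  }
  out
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
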