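# File formats: FASTA (via Biostrings, wrapped at 60 columns), strict 4-line
# FASTQ (optionally gzipped), BED-like sub-region TSV (0-based half-open),
# and commented TSV tables.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (strict 4-line records)
#'
#' Multiline/wrapped FASTQ is rejected; malformed records error with the
#' offending line number. Gzipped input is handled transparently.
#'
#' @param path file path (.fastq or .fastq.gz).
#' @return list(seq, name) character vectors.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4 != 0)
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4 (near line ",
         n, ")")
  if (n == 0) return(list(seq = character(0), name = character(0)))
  heads <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  quals <- lines[seq(4, n, by = 4)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stop("malformed FASTQ record: missing '@' at line ", (bad[1] - 1) * 4 + 1)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record: missing '+' at line ", (bad[1] - 1) * 4 + 3)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record: sequence/quality length mismatch at line ",
         (bad[1] - 1) * 4 + 2)
  list(seq = seqs, name = sub("^@", "", heads))
}

#' Read a FASTQ pair into a read library
#'
#' @param path_r1,path_r2 mate FASTQ paths.
#' @return a `read_library`.
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  a <- read_fastq(path_r1)
  b <- read_fastq(path_r2)
  if (length(a$seq) != length(b$seq))
    stop("mate files differ in record count")
  read_library(a$seq, b$seq, names = sub("/[12]$", "", a$name))
}

#' Write a read library as paired FASTQ
#'
#' Constant Phred-33 quality ('I' = Q40).
#'
#' @param lib a `read_library`.
#' @param path_r1,path_r2 output paths; `.gz` suffix enables gzip.
#' @param qual_char constant quality character.
#' @return invisible c(path_r1, path_r2).
#' @export
write_fastq <- function(lib, path_r1, path_r2, qual_char = "I") {
  stopifnot(inherits(lib, "read_library"))
  wr <- function(seqs, names, suffix, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    out <- character(4 * length(seqs))
    out[seq(1, length(out), 4)] <- paste0("@", names, suffix)
    out[seq(2, length(out), 4)] <- seqs
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- vapply(nchar(seqs), function(n)
      strrep(qual_char, n), character(1))
    writeLines(out, con)
  }
  wr(lib$r1, lib$names, "/1", path_r1)
  wr(lib$r2, lib$names, "/2", path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read BED-like sub-region annotations
#'
#' Tab-separated, 0-based half-open: monomer_id, start, end, label. Intervals
#' are validated against `monomer_lengths` when provided.
#'
#' @param path file path.
#' @param monomer_lengths optional named integer vector of monomer lengths.
#' @return data.frame (monomer_id, start, end, label).
#' @export
read_bedlike <- function(path, monomer_lengths = NULL) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("monomer_id", "start", "end", "label"),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("invalid interval (need 0 <= start < end) in ", path)
  if (!is.null(monomer_lengths)) {
    for (i in seq_len(nrow(df))) {
      L <- monomer_lengths[[df$monomer_id[i]]]
      if (is.null(L) || is.na(L))
        stop("unknown monomer '", df$monomer_id[i], "' in ", path)
      if (df$end[i] > L)
        stop("interval end ", df$end[i], " exceeds monomer '",
             df$monomer_id[i], "' length ", L)
    }
  }
  df
}

#' Write a TSV table with optional header comments
#'
#' @param table data.frame.
#' @param path output path.
#' @param comment optional character vector written as `# ` header lines
#'   (column units etc.).
#' @return the path, invisibly.
#' @export
write_tsv <- function(table, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
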