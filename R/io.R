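# Standard-format readers and writers shared by the pipeline.

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first record character (`>` FASTA,
#' `@` FASTQ).  FASTQ quality scores are parsed but unused: recruitment
#' treats every read individually and works from the called bases only.
#'
#' @param path input file path.
#' @return A named character vector of uppercase read sequences.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(setNames(character(0), character(0)))
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(x))
  # Biostrings keeps full headers; use the first token as the read id
  names(out) <- vapply(strsplit(names(out), "[ \t]"), `[`, character(1), 1L)
  out
}

#' Write reads as FASTA
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  reads <- as_read_vector(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0L)
    writeLines(paste0(">", names(reads), "\n", unname(reads)), con)
  invisible(path)
}

# TSV writer with optional '#' comment header lines (units, denominators)
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(comments, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
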