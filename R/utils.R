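# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Controlled vocabulary of coarse plankton group labels
#'
#' The group labels used throughout the package for aggregation,
#' classification and plotting.  `heterotrophic_bacteria` is included so that
#' bacterioplankton communities mixing cyanobacteria with non-photosynthetic
#' bacteria can be simulated and profiled.
#'
#' @return Character vector of valid group labels.
#' @export
plankton_groups <- function() {
  c("Prochlorococcus", "Synechococcus", "diatoms", "dinoflagellates",
    "haptophytes", "chlorophytes", "pelagophytes",
    "heterotrophic_bacteria", "other")
}

#' Marker gene labels understood by the package
#'
#' psbO is the phytoplankton quantification marker; recA and the 25
#' ribosomal-protein genes (rp01..rp25) are the single-copy housekeeping
#' denominators; petC_chloroplast / rieske_mitochondrial are the paired
#' Rieske subunits; the rRNA genes are the copy-number-biased ribotype
#' markers used for comparison.
#'
#' @return Character vector of valid gene labels.
#' @export
marker_genes <- function() {
  c("psbO", "recA", sprintf("rp%02d", 1:25),
    "petC_chloroplast", "rieske_mitochondrial", "rRNA_16S", "rRNA_18S")
}

#' Size-fraction labels
#'
#' The five filter-membrane size fractions (in micrometres) used to partition
#' plankton samples by body size.
#'
#' @return Character vector of valid size-fraction labels.
#' @export
size_fractions <- function() {
  c("0.2-3", "0.8-5", "5-20", "20-180", "180-2000")
}

# byte-wise (locale-independent) sorting, used wherever determinism matters
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")

# split a semicolon-joined taxonomy path into rank labels
split_taxonomy <- function(x) strsplit(x, ";", fixed = TRUE)

# longest common rank prefix of a list of rank vectors
taxonomy_lca <- function(paths) {
  if (length(paths) == 0L) return(character(0))
  if (length(paths) == 1L) return(paths[[1]])
  ref <- paths[[1]]
  k <- length(ref)
  for (p in paths[-1]) {
    k <- min(k, length(p))
    while (k > 0L && !identical(ref[seq_len(k)], p[seq_len(k)])) k <- k - 1L
    if (k == 0L) break
  }
  ref[seq_len(k)]
}

# uppercase, map U to T, map IUPAC ambiguity letters to N; error on anything
# that is not a letter or gap
clean_nucleotides <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^A-Z]", x)
  if (any(bad))
    stop("non-letter characters in ", what, call. = FALSE)
  gsub("[^ACGT]", "N", x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# reads can be given as a named character vector, a data.frame with
# read_id/sequence columns, or a Biostrings XStringSet
as_read_vector <- function(reads) {
  if (methods::is(reads, "XStringSet")) {
    out <- as.character(reads)
  } else if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    out <- setNames(as.character(reads$sequence), reads$read_id)
  } else if (is.character(reads)) {
    out <- reads
  } else stop("unsupported reads object", call. = FALSE)
  if (is.null(names(out)) && length(out) > 0L)
    names(out) <- sprintf("read%06d", seq_along(out))
  toupper(out)
}

reverse_complement <- function(x) .revcomp_cpp(x)
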