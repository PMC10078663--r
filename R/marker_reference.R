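# Reference database data model, FASTA parsing, redundancy clustering and
# validation.
#
# Header dialect: >record_id|gene|group|rank1;rank2;...
# The group field must come from plankton_groups(); ranks run from domain to
# species and may have variable depth.

#' Construct a marker reference database
#'
#' @param records data.frame with columns `record_id`, `gene`, `group`,
#'   `taxonomy` (semicolon-joined rank labels, domain first), `sequence`.
#' @param gene gene label shared by all records (see [marker_genes()]).
#' @param provenance free-text metadata carried along with the database.
#'
#' @return An object of class `reference_db`: a list with elements `gene`,
#'   `records` (with `length_bp` added) and `provenance`.
#' @export
reference_db <- function(records, gene = NULL, provenance = "") {
  stopifnot(is.data.frame(records))
  needed <- c("record_id", "gene", "group", "taxonomy", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L)
    stopf("records is missing columns: %s", paste(missing_cols, collapse = ", "))
  records$record_id <- as.character(records$record_id)
  records$sequence <- clean_nucleotides(as.character(records$sequence))
  records$length_bp <- nchar(records$sequence)
  if (any(records$length_bp == 0L))
    stopf("empty sequence for record '%s'",
          records$record_id[which(records$length_bp == 0L)[1]])
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0L)
    stopf("duplicate record id '%s'", dup[1])
  if (is.null(gene)) {
    gene <- unique(records$gene)
    if (length(gene) != 1L)
      stop("records carry multiple gene labels; supply `gene` explicitly ",
           "or split the database", call. = FALSE)
  }
  if (!gene %in% marker_genes())
    stopf("unknown gene label '%s'", gene)
  off <- records$record_id[records$gene != gene]
  if (length(off) > 0L)
    stopf("record '%s' has gene label '%s', database is '%s'",
          off[1], records$gene[records$gene != gene][1], gene)
  bad_group <- setdiff(unique(records$group), plankton_groups())
  if (length(bad_group) > 0L)
    stopf("unknown group label '%s'", bad_group[1])
  empty_rank <- vapply(split_taxonomy(records$taxonomy),
                       function(r) length(r) == 0L || any(!nzchar(r)),
                       logical(1))
  if (any(empty_rank))
    stopf("empty taxonomy rank in record '%s'",
          records$record_id[which(empty_rank)[1]])
  rownames(records) <- NULL
  structure(list(gene = gene,
                 records = records[, c("record_id", "gene", "group",
                                       "taxonomy", "sequence", "length_bp")],
                 provenance = provenance),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d %s sequences (%d-%d bp)\n",
              nrow(x$records), x$gene,
              if (nrow(x$records)) min(x$records$length_bp) else 0L,
              if (nrow(x$records)) max(x$records$length_bp) else 0L))
  invisible(x)
}

#' Parse a marker reference FASTA
#'
#' Reads a (possibly line-wrapped) FASTA whose headers follow the dialect
#' `>id|gene|group|rank1;rank2;...`.  Sequences are uppercased, U is mapped
#' to T, and IUPAC ambiguity letters are mapped to N.
#'
#' @param path path to a FASTA file, or a character vector of FASTA lines.
#' @param gene expected gene label; defaults to the label found in the
#'   headers (which must then be unique).
#' @param provenance free-text metadata stored on the database.
#'
#' @return A [reference_db()].
#' @export
parse_reference_fasta <- function(path, gene = NULL, provenance = NULL) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    provenance <- provenance %||% path
    readLines(path)
  } else {
    if (length(path) == 1L) path <- strsplit(path, "\n", fixed = TRUE)[[1]]
    path
  }
  provenance <- provenance %||% ""
  lines <- sub("\r$", "", lines)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L)
    stop("no FASTA headers found", call. = FALSE)
  pre <- lines[seq_len(hdr_idx[1] - 1L)]
  if (any(nzchar(trimws(pre))))
    stopf("sequence data before first header at line %d",
          which(nzchar(trimws(pre)))[1])
  n <- length(hdr_idx)
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  ids <- genes <- groups <- tax <- seqs <- character(n)
  for (k in seq_len(n)) {
    line_no <- hdr_idx[k]
    hdr <- sub("^>", "", lines[line_no])
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(parts) != 4L || any(!nzchar(parts)))
      stopf("malformed header at line %d: expected 'id|gene|group|ranks'",
            line_no)
    ids[k] <- parts[1]; genes[k] <- parts[2]; groups[k] <- parts[3]
    tax[k] <- parts[4]
    body <- if (ends[k] >= line_no + 1L)
      lines[seq.int(line_no + 1L, ends[k])] else character(0)
    seqs[k] <- gsub("[ \t]", "", paste(body, collapse = ""))
    if (!nzchar(seqs[k]))
      stopf("empty sequence for record '%s' (line %d)", ids[k], line_no)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stopf("duplicate record id '%s'", dup[1])
  reference_db(data.frame(record_id = ids, gene = genes, group = groups,
                          taxonomy = tax, sequence = seqs,
                          stringsAsFactors = FALSE),
               gene = gene, provenance = provenance)
}

#' Write a reference database as FASTA
#'
#' Inverse of [parse_reference_fasta()]; round-trips bit-identically on
#' sequences and taxonomy.
#'
#' @param db a [reference_db()].
#' @param path output file path.
#' @param width line-wrap width for sequences (0 = no wrapping).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path, width = 70L) {
  stopifnot(inherits(db, "reference_db"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(db$records))) {
    r <- db$records[k, ]
    writeLines(sprintf(">%s|%s|%s|%s", r$record_id, r$gene, r$group,
                       r$taxonomy), con)
    s <- r$sequence
    if (width > 0L) {
      starts <- seq.int(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Global (end-gap-free) nucleotide identity between two sequences
#'
#' Identity is matches / alignment columns of an overlap (end-gap-free
#' global) alignment under the package's nucleotide scoring (+1 match, -1
#' mismatch, gap open -2, extend -1).  N never counts as a match.
#'
#' @param a,b nucleotide strings.
#' @return Identity as a fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  submat <- nucleotide_submat()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = submat, gapOpening = 1, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cols <- length(p)
  if (cols == 0L) return(0)
  matches <- sum(p == s & p %in% c("A", "C", "G", "T"))
  matches / cols
}

nucleotide_submat <- function(match = 1, mismatch = -1) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N never matches
  m
}

#' Cluster a reference database at an identity cutoff
#'
#' Greedy incremental redundancy clustering in the style of cd-hit: records
#' are sorted by decreasing length (ties broken by id), and each record joins
#' the first existing cluster whose representative it matches at >= the
#' cutoff global (end-gap-free) identity, otherwise it founds a new cluster.
#'
#' @param db a [reference_db()].
#' @param identity_cutoff identity threshold as a fraction in (0, 1];
#'   default 0.80, the conventional redundancy-reduction cutoff.
#'
#' @return A list with `db` (representatives only, original record order
#'   preserved) and `clusters`, a data.frame mapping `member` to
#'   `representative`.
#' @export
cluster_redundant <- function(db, identity_cutoff = 0.80) {
  stopifnot(inherits(db, "reference_db"))
  if (!is.numeric(identity_cutoff) || length(identity_cutoff) != 1L ||
      identity_cutoff <= 0 || identity_cutoff > 1)
    stop("identity_cutoff must be in (0, 1]", call. = FALSE)
  rec <- db$records
  if (nrow(rec) == 0L)
    return(list(db = db,
                clusters = data.frame(member = character(0),
                                      representative = character(0))))
  ord <- order(-rec$length_bp, rec$record_id, method = "radix")
  reps <- integer(0)        # row indices (in rec) of representatives
  member_of <- character(nrow(rec))
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      if (alignment_identity(rec$sequence[i], rec$sequence[r]) >=
          identity_cutoff) {
        member_of[i] <- rec$record_id[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      member_of[i] <- rec$record_id[i]
    }
  }
  keep <- sort(reps)
  out_db <- reference_db(rec[keep, setdiff(names(rec), "length_bp")],
                         gene = db$gene, provenance = db$provenance)
  list(db = out_db,
       clusters = data.frame(member = rec$record_id,
                             representative = member_of,
                             stringsAsFactors = FALSE))
}

#' Validate a reference database
#'
#' Report-only quality control: per-group record counts, length summary,
#' overall N fraction, and flags for records with more than 10% N or shorter
#' than 60 nt (below the resolvable marker-fragment floor).
#'
#' @param db a [reference_db()].
#' @return A list of class `db_validation` with elements `n_records`,
#'   `per_group`, `length_min`, `length_mean`, `length_max`, `n_fraction`
#'   and `flagged` (data.frame of record_id, reason).
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  rec <- db$records
  n_chars <- vapply(gregexpr("N", rec$sequence, fixed = TRUE),
                    function(m) sum(m > 0L), integer(1))
  n_frac_rec <- ifelse(rec$length_bp > 0, n_chars / rec$length_bp, 0)
  flagged <- rbind(
    data.frame(record_id = rec$record_id[rec$length_bp < 60L],
               reason = "short", stringsAsFactors = FALSE),
    data.frame(record_id = rec$record_id[n_frac_rec > 0.10],
               reason = "high_N", stringsAsFactors = FALSE))
  per_group <- as.data.frame(table(group = rec$group),
                             stringsAsFactors = FALSE)
  names(per_group)[2] <- "n"
  structure(list(
    n_records = nrow(rec),
    per_group = per_group,
    length_min = if (nrow(rec)) min(rec$length_bp) else NA_integer_,
    length_mean = if (nrow(rec)) mean(rec$length_bp) else NA_real_,
    length_max = if (nrow(rec)) max(rec$length_bp) else NA_integer_,
    n_fraction = if (nrow(rec)) sum(n_chars) / sum(rec$length_bp) else NA_real_,
    flagged = flagged), class = "db_validation")
}

#' @export
print.db_validation <- function(x, ...) {
  cat(sprintf("db_validation: %d records, length %s-%s (mean %.1f), N %.3f%%\n",
              x$n_records, x$length_min, x$length_max, x$length_mean,
              100 * x$n_fraction))
  if (nrow(x$flagged)) {
    cat("flagged records:\n")
    print(x$flagged, row.names = FALSE)
  }
  invisible(x)
}
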