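# Read recruitment: align metagenomic reads against marker reference
# databases and apply the recruitment filters (minimum read size, identity,
# aligned fraction of the read, and k-mer complexity), plus the simplified
# rRNA "miTag" best-hit/LCA classifier.

#' Recruitment filter and scoring parameters
#'
#' Defaults are the standard short-read recruitment thresholds: minimum read
#' size 70 bp, >= 80% identity, >= 80% of the read aligned, and a 3-mer
#' complexity filter parameterized by 75 (dominant-kmer percent) and 30
#' (minimum distinct k-mers).  The alignment scoring scheme (+1 match, -1
#' mismatch, gap open -2, gap extend -1; a gap of length L costs
#' `gap_open + (L-1) * gap_extend`) is a package default, not a threshold.
#'
#' @param min_read_size minimum read length in bp.
#' @param min_identity minimum percent identity over alignment columns.
#' @param min_aligned_fraction minimum percent of the read length inside the
#'   alignment.
#' @param complexity_percent a read fails if its most frequent k-mer occupies
#'   at least this percentage of all k-mer windows.
#' @param complexity_number a read fails if it has fewer distinct k-mers than
#'   this.
#' @param kmer_size_complexity k-mer size for the complexity filter.
#' @param match,mismatch,gap_open,gap_extend alignment scores (integers).
#'
#' @return An object of class `recruitment_params`.
#' @export
recruitment_params <- function(min_read_size = 70L, min_identity = 80,
                               min_aligned_fraction = 80,
                               complexity_percent = 75,
                               complexity_number = 30L,
                               kmer_size_complexity = 3L,
                               match = 1L, mismatch = -1L,
                               gap_open = -2L, gap_extend = -1L) {
  if (!is.numeric(min_read_size) || min_read_size < 1)
    stop("min_read_size must be >= 1", call. = FALSE)
  for (nm in c("min_identity", "min_aligned_fraction", "complexity_percent")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 100)
      stopf("%s must be a percentage in (0, 100]", nm)
  }
  if (complexity_number < 1) stop("complexity_number must be >= 1",
                                  call. = FALSE)
  if (kmer_size_complexity < 1 || kmer_size_complexity > 8)
    stop("kmer_size_complexity must be in 1..8", call. = FALSE)
  structure(list(min_read_size = as.integer(min_read_size),
                 min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 complexity_percent = complexity_percent,
                 complexity_number = as.integer(complexity_number),
                 kmer_size_complexity = as.integer(kmer_size_complexity),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "recruitment_params")
}

#' k-mer complexity filter for a single read
#'
#' A read fails when it has fewer distinct k-mers than `complexity_number`,
#' or when its most frequent k-mer occupies at least `complexity_percent` of
#' all k-mer windows.  Windows containing N are not counted.  This catches
#' homopolymer and short-repeat reads deterministically.
#'
#' @param read a nucleotide string.
#' @param params a [recruitment_params()].
#' @return A list with `pass` (logical) and `reason` (`"ok"`,
#'   `"too_short_for_complexity"`, `"low_distinct_kmers"` or
#'   `"dominant_kmer"`).
#' @export
complexity_pass <- function(read, params = recruitment_params()) {
  k <- params$kmer_size_complexity
  if (nchar(read) < k)
    return(list(pass = FALSE, reason = "too_short_for_complexity"))
  st <- .kmer_stats_cpp(toupper(read), k)
  distinct <- st[1]; max_count <- st[2]; windows <- st[3]
  if (windows == 0L)
    return(list(pass = FALSE, reason = "low_distinct_kmers"))
  if (distinct < params$complexity_number)
    return(list(pass = FALSE, reason = "low_distinct_kmers"))
  if (100 * max_count / windows >= params$complexity_percent)
    return(list(pass = FALSE, reason = "dominant_kmer"))
  list(pass = TRUE, reason = "ok")
}

# vectorized internal version; returns reason ("ok" = pass) per read
complexity_reason_vec <- function(reads, params) {
  k <- params$kmer_size_complexity
  vapply(reads, function(s) complexity_pass(s, params)$reason, character(1),
         USE.NAMES = FALSE)
}

#' Best local alignment of a read against one reference
#'
#' Full Smith-Waterman local alignment of the read and of its reverse
#' complement against the reference; the higher-scoring strand wins (forward
#' preferred on ties).  Identity is matches / alignment columns; the aligned
#' read fraction is the proportion of read bases inside the alignment.
#' Coordinates are 0-based half-open on the forward reference strand.
#'
#' @param read a nucleotide string.
#' @param reference a nucleotide string, or a single-record slice of a
#'   [reference_db()]'s `records`.
#' @param params a [recruitment_params()] (scoring scheme is taken from it).
#' @return A list of class `alignment_hit` with `score`, `identity` (percent),
#'   `aligned_read_fraction` (percent), `matches`, `columns`, `ref_start`,
#'   `ref_end`, `read_start`, `read_end`, `strand`; or `NULL` if no alignment
#'   scores above 0.
#' @export
align_read <- function(read, reference, params = recruitment_params()) {
  if (is.data.frame(reference)) reference <- reference$sequence[1]
  read <- toupper(read); reference <- toupper(reference)
  fwd <- .sw_align_cpp(read, reference, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  rev <- .sw_align_cpp(reverse_complement(read), reference, params$match,
                       params$mismatch, params$gap_open, params$gap_extend)
  if (!fwd$found && !rev$found) return(NULL)
  use_rev <- rev$found && (!fwd$found || rev$score > fwd$score)
  a <- if (use_rev) rev else fwd
  structure(list(score = a$score,
                 identity = 100 * a$matches / a$columns,
                 aligned_read_fraction =
                   100 * (a$read_end - a$read_start) / nchar(read),
                 matches = a$matches, columns = a$columns,
                 ref_start = a$ref_start, ref_end = a$ref_end,
                 read_start = a$read_start, read_end = a$read_end,
                 strand = if (use_rev) "-" else "+"),
            class = "alignment_hit")
}

#' Recruit reads to one or more marker reference databases
#'
#' A read is recruited iff it is at least `min_read_size` long, passes the
#' complexity filter, and its best hit over all references (highest
#' Smith-Waterman score; ties broken by higher identity, then longer
#' alignment, then lexicographically smallest reference id, then forward
#' strand) reaches both the identity and the aligned-fraction thresholds.
#' Rejection reasons are recorded per read (`too_short`, `low_complexity`,
#' `no_hit`, `low_identity`, `low_coverage`).
#'
#' @param reads a named character vector of reads (or data.frame /
#'   DNAStringSet; see [read_reads()]).
#' @param db a [reference_db()] or a list of them; with several databases
#'   reads compete across all references and `total_mapped_reads` counts
#'   reads recruited to any of them.
#' @param params a [recruitment_params()].
#'
#' @return An object of class `recruitment_result`: list with `hits`
#'   (one row per recruited read), `rejected` (read_id, reason),
#'   `total_input_reads`, `total_mapped_reads`, `params`.
#' @export
recruit <- function(reads, db, params = recruitment_params()) {
  if (inherits(db, "reference_db")) db <- list(db)
  stopifnot(all(vapply(db, inherits, logical(1), "reference_db")))
  rec <- do.call(rbind, lapply(db, function(d)
    d$records[, c("record_id", "gene", "group", "taxonomy", "sequence",
                  "length_bp")]))
  if (nrow(rec) == 0L) stop("empty reference database", call. = FALSE)
  dup <- rec$record_id[duplicated(rec$record_id)]
  if (length(dup) > 0L)
    stopf("duplicate record id across databases: '%s'", dup[1])
  rec <- rec[order_c(rec$record_id), , drop = FALSE]

  reads <- as_read_vector(reads)
  n <- length(reads)
  empty_hits <- data.frame(
    read_id = character(0), reference_id = character(0), gene = character(0),
    group = character(0), identity = numeric(0),
    aligned_read_fraction = numeric(0), ref_start = integer(0),
    ref_end = integer(0), strand = character(0), score = integer(0),
    matches = integer(0), columns = integer(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(list(hits = empty_hits,
                          rejected = data.frame(read_id = character(0),
                                                reason = character(0)),
                          total_input_reads = 0L, total_mapped_reads = 0L,
                          params = params),
                     class = "recruitment_result"))

  reason <- rep(NA_character_, n)
  len <- nchar(reads)
  reason[len < params$min_read_size] <- "too_short"
  todo <- which(is.na(reason))
  if (length(todo) > 0L) {
    cx <- complexity_reason_vec(reads[todo], params)
    reason[todo[cx != "ok"]] <- "low_complexity"
  }
  todo <- which(is.na(reason))

  hits <- empty_hits
  if (length(todo) > 0L) {
    best <- .recruit_best_cpp(unname(reads[todo]), rec$sequence,
                              params$match, params$mismatch,
                              params$gap_open, params$gap_extend)
    identity <- ifelse(best$columns > 0, 100 * best$matches / best$columns, 0)
    frac <- 100 * (best$read_end - best$read_start) / len[todo]
    ok <- best$found & identity >= params$min_identity &
      frac >= params$min_aligned_fraction
    reason[todo[!best$found]] <- "no_hit"
    low_id <- best$found & identity < params$min_identity
    reason[todo[low_id]] <- "low_identity"
    low_cov <- best$found & !low_id & frac < params$min_aligned_fraction
    reason[todo[low_cov]] <- "low_coverage"
    keep <- which(ok)
    if (length(keep) > 0L) {
      ri <- best$ref_idx[keep]
      hits <- data.frame(
        read_id = names(reads)[todo[keep]],
        reference_id = rec$record_id[ri],
        gene = rec$gene[ri],
        group = rec$group[ri],
        identity = identity[keep],
        aligned_read_fraction = frac[keep],
        ref_start = best$ref_start[keep],
        ref_end = best$ref_end[keep],
        strand = as.character(best$strand[keep]),
        score = best$score[keep],
        matches = best$matches[keep],
        columns = best$columns[keep],
        stringsAsFactors = FALSE)
    }
  }
  rejected <- data.frame(read_id = names(reads)[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  structure(list(hits = hits, rejected = rejected,
                 total_input_reads = n,
                 total_mapped_reads = nrow(hits),
                 params = params),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("recruitment_result: %d/%d reads recruited\n",
              nrow(x$hits), x$total_input_reads))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    cat("rejections:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write recruitment results as TSV
#'
#' @param result a [recruit()] result.
#' @param hits_path,rejected_path output file paths (`NULL` to skip one).
#' @return `invisible(result)`.
#' @export
write_recruitment_tsv <- function(result, hits_path, rejected_path = NULL) {
  stopifnot(inherits(result, "recruitment_result"))
  hdr <- c("# read recruitment best hits",
           "# identity: percent matches over alignment columns;",
           "# aligned_fraction: percent of read bases inside the alignment;",
           "# ref coordinates: 0-based half-open, forward strand")
  cols <- c("read_id", "reference_id", "identity", "aligned_read_fraction",
            "ref_start", "ref_end", "strand", "score")
  write_tsv(result$hits[, cols], hits_path, comments = hdr)
  if (!is.null(rejected_path))
    write_tsv(result$rejected, rejected_path,
              comments = "# reads rejected by the recruitment filters")
  invisible(result)
}

#' Classify an rRNA fragment by best hit with LCA tie-breaking (miTag rule)
#'
#' Fragments shorter than `min_len` or containing any N are rejected.  The
#' best hit is the reference with the fewest differences (mismatches plus gap
#' columns) in an alignment covering 100% of the fragment; only hits with
#' identity of at least `min_identity` percent (identity = 100 x (length -
#' differences) / length) are kept.  When several references tie on the
#' number of differences, the fragment is assigned the last common ancestor
#' (longest shared rank prefix) of the tied references.
#'
#' @param read a nucleotide string.
#' @param ribo_db a [reference_db()] of rRNA ribotypes.
#' @param min_len minimum fragment length (bp).
#' @param min_identity minimum percent identity.
#' @param read_id identifier carried into the result.
#' @return A list of class `lca_assignment` with `read_id`, `taxonomy`
#'   (character vector of ranks, possibly truncated), `n_tied_hits`,
#'   `best_reference_ids`, `differences`; or a list with `rejected = TRUE`
#'   and a `reason` (`"too_short"`, `"contains_N"` or `"no_hit"`).
#' @export
classify_ribotag <- function(read, ribo_db, min_len = 100L,
                             min_identity = 80, read_id = "query") {
  stopifnot(inherits(ribo_db, "reference_db"))
  read <- toupper(read)
  if (nchar(read) < min_len)
    return(list(rejected = TRUE, reason = "too_short", read_id = read_id))
  if (grepl("N", read, fixed = TRUE))
    return(list(rejected = TRUE, reason = "contains_N", read_id = read_id))
  rec <- ribo_db$records
  rev <- reverse_complement(read)
  diffs <- vapply(rec$sequence, function(ref)
    min(.fit_diffs_cpp(read, ref), .fit_diffs_cpp(rev, ref)),
    integer(1), USE.NAMES = FALSE)
  identity <- 100 * (nchar(read) - diffs) / nchar(read)
  ok <- identity >= min_identity
  if (!any(ok))
    return(list(rejected = TRUE, reason = "no_hit", read_id = read_id))
  dmin <- min(diffs[ok])
  tied <- which(ok & diffs == dmin)
  tied <- tied[order_c(rec$record_id[tied])]
  tax <- if (length(tied) == 1L) {
    split_taxonomy(rec$taxonomy[tied])[[1]]
  } else {
    taxonomy_lca(split_taxonomy(rec$taxonomy[tied]))
  }
  structure(list(read_id = read_id, taxonomy = tax,
                 n_tied_hits = length(tied),
                 best_reference_ids = rec$record_id[tied],
                 differences = dmin, rejected = FALSE),
            class = "lca_assignment")
}
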