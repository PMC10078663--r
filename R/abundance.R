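# rpkm abundance profiles: coverage statistics, rpkm conversion, taxon
# aggregation, and relative abundances over declared denominator sets.
#
# rpkm = reads per kilobase covered per million mapped reads, where
# "kilobase covered" is the size of the union of alignment intervals on the
# reference (bases touched by at least one read), not the full gene length.

#' Per-reference coverage statistics from a recruitment result
#'
#' `covered_bases` is the size of the union of `[ref_start, ref_end)` hit
#' intervals on each reference.  References without hits are kept with zero
#' counts so abundance tables align across samples.
#'
#' @param result a [recruit()] result.
#' @param db the [reference_db()] (or list of them) the reads were recruited
#'   to.
#' @return data.frame with `reference_id`, `gene`, `group`, `taxonomy`,
#'   `n_reads`, `covered_bases`, `gene_length_bp`.
#' @export
coverage_stats <- function(result, db) {
  stopifnot(inherits(result, "recruitment_result"))
  if (inherits(db, "reference_db")) db <- list(db)
  rec <- do.call(rbind, lapply(db, function(d)
    d$records[, c("record_id", "gene", "group", "taxonomy", "length_bp")]))
  unknown <- setdiff(result$hits$reference_id, rec$record_id)
  if (length(unknown) > 0L)
    stopf("hit to unknown reference '%s'", unknown[1])
  n_reads <- table(factor(result$hits$reference_id, levels = rec$record_id))
  covered <- setNames(integer(nrow(rec)), rec$record_id)
  if (nrow(result$hits) > 0L) {
    by_ref <- split(result$hits[, c("ref_start", "ref_end")],
                    result$hits$reference_id)
    for (id in names(by_ref)) {
      ir <- IRanges::IRanges(start = by_ref[[id]]$ref_start + 1L,
                             end = by_ref[[id]]$ref_end)
      covered[id] <- sum(IRanges::width(IRanges::reduce(ir)))
    }
  }
  data.frame(reference_id = rec$record_id, gene = rec$gene,
             group = rec$group, taxonomy = rec$taxonomy,
             n_reads = as.integer(n_reads),
             covered_bases = as.integer(covered),
             gene_length_bp = rec$length_bp,
             stringsAsFactors = FALSE)
}

#' rpkm: reads per kilobase covered per million mapped reads
#'
#' `rpkm = n_reads / ((covered_bases / 1000) * (total_mapped_reads / 1e6))`,
#' with rpkm defined as 0 where `n_reads` is 0.
#'
#' @param n_reads reads recruited to the reference (vectorized).
#' @param covered_bases bases of the reference covered by at least one read.
#' @param total_mapped_reads reads recruited to any database in the run
#'   (must be > 0).
#' @return Numeric rpkm value(s).
#' @export
rpkm <- function(n_reads, covered_bases, total_mapped_reads) {
  if (length(total_mapped_reads) != 1L || !is.finite(total_mapped_reads) ||
      total_mapped_reads <= 0)
    stop("total_mapped_reads must be a single positive number",
         call. = FALSE)
  ifelse(n_reads == 0, 0,
         n_reads / ((covered_bases / 1000) * (total_mapped_reads / 1e6)))
}

#' Build a per-reference rpkm abundance table
#'
#' @param stats output of [coverage_stats()].
#' @param total_mapped_reads denominator for the per-million normalization;
#'   defaults to the sum of `n_reads` in `stats`.
#' @param sample_id,size_fraction sample annotation; `size_fraction` must be
#'   one of [size_fractions()].
#' @param length_normalization `"covered"` (default; kilobases covered) or
#'   `"gene"` (full gene length) for sensitivity analysis.
#' @return data.frame of class `abundance_table` with columns of `stats`
#'   plus `rpkm`, and attributes `sample_id`, `size_fraction`,
#'   `total_mapped_reads`.
#' @export
abundance_table <- function(stats, total_mapped_reads = NULL,
                            sample_id = "sample1", size_fraction = "0.2-3",
                            length_normalization = c("covered", "gene")) {
  length_normalization <- match.arg(length_normalization)
  if (!size_fraction %in% size_fractions())
    stopf("size_fraction must be one of: %s",
          paste(size_fractions(), collapse = ", "))
  total_mapped_reads <- total_mapped_reads %||% sum(stats$n_reads)
  denom_bases <- if (length_normalization == "covered")
    stats$covered_bases else stats$gene_length_bp
  out <- stats
  out$rpkm <- rpkm(stats$n_reads, denom_bases, total_mapped_reads)
  structure(out, sample_id = sample_id, size_fraction = size_fraction,
            total_mapped_reads = total_mapped_reads,
            class = c("abundance_table", "data.frame"))
}

#' Aggregate an abundance table by taxon
#'
#' Taxon rpkm is the sum of its member references' rpkm ("per-sequence rpkm
#' then sum").  References without a resolvable label land in
#' `"unclassified"`.
#'
#' @param table an [abundance_table()] (per reference).
#' @param by `"group"` (default) to aggregate by the coarse group label, or
#'   an integer rank depth to aggregate by the taxonomy rank at that depth.
#' @return An `abundance_table` keyed by `taxon`.
#' @export
aggregate_by_taxon <- function(table, by = "group") {
  key <- if (identical(by, "group")) {
    table$group
  } else if (is.numeric(by)) {
    vapply(split_taxonomy(table$taxonomy), function(r)
      if (length(r) >= by) r[[by]] else NA_character_, character(1))
  } else stop("`by` must be \"group\" or a rank depth", call. = FALSE)
  key[is.na(key) | !nzchar(key)] <- "unclassified"
  if (nrow(table) == 0L) {
    out <- data.frame(taxon = character(0), n_reads = integer(0),
                      rpkm = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- aggregate(cbind(n_reads, rpkm) ~ taxon,
                     data = data.frame(taxon = key, n_reads = table$n_reads,
                                       rpkm = table$rpkm), FUN = sum)
    out <- out[order_c(out$taxon), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, sample_id = attr(table, "sample_id"),
            size_fraction = attr(table, "size_fraction"),
            total_mapped_reads = attr(table, "total_mapped_reads"),
            class = c("abundance_table", "data.frame"))
}

#' Group labels counted as cyanobacteria
#'
#' @return Character vector of the picocyanobacterial group labels.
#' @export
cyanobacteria_groups <- function() c("Prochlorococcus", "Synechococcus")

#' Relative abundances over a declared denominator set
#'
#' Converts taxon rpkm values to percentages of a denominator community:
#' `"total_phytoplankton"` (all taxa in the table),
#' `"eukaryotic_phytoplankton"` (all taxa except the cyanobacterial groups),
#' or `"picophytoplankton"` (Prochlorococcus + Synechococcus + the declared
#' picoeukaryote groups).  A custom character vector of taxa is also
#' accepted.  The table is restricted to the denominator taxa, so
#' percentages sum to 100.
#'
#' @param aggregate a taxon-level [abundance_table()] (see
#'   [aggregate_by_taxon()]).
#' @param denominator_set one of the labels above or a character vector of
#'   taxa.
#' @param picoeukaryote_groups groups counted as eukaryotic
#'   picophytoplankton for the `"picophytoplankton"` denominator.
#' @return data.frame of class `relative_abundance_table` with `taxon`,
#'   `rpkm`, `percent`, and attributes `denominator_set` and `undefined`
#'   (TRUE when the denominator total is zero, in which case `percent` is NA
#'   rather than NaN).
#' @export
relative_abundance <- function(aggregate,
                               denominator_set = "total_phytoplankton",
                               picoeukaryote_groups = c("chlorophytes",
                                                        "pelagophytes")) {
  stopifnot(is.data.frame(aggregate), "taxon" %in% names(aggregate))
  taxa <- aggregate$taxon
  keep <- if (length(denominator_set) == 1L &&
              denominator_set %in% c("total_phytoplankton",
                                     "eukaryotic_phytoplankton",
                                     "picophytoplankton")) {
    switch(denominator_set,
           total_phytoplankton = taxa,
           eukaryotic_phytoplankton = setdiff(taxa, cyanobacteria_groups()),
           picophytoplankton = intersect(taxa, c(cyanobacteria_groups(),
                                                 picoeukaryote_groups)))
  } else if (is.character(denominator_set)) {
    miss <- setdiff(denominator_set, taxa)
    if (length(miss) > 0L)
      stopf("denominator taxon '%s' absent from the table", miss[1])
    denominator_set
  } else stop("unknown denominator_set", call. = FALSE)
  sub <- aggregate[aggregate$taxon %in% keep, , drop = FALSE]
  total <- sum(sub$rpkm)
  undefined <- !is.finite(total) || total <= 0
  sub$percent <- if (undefined) NA_real_ else 100 * sub$rpkm / total
  rownames(sub) <- NULL
  structure(sub[, c("taxon", "rpkm", "percent")],
            denominator_set = paste(denominator_set, collapse = "+"),
            undefined = undefined,
            sample_id = attr(aggregate, "sample_id"),
            size_fraction = attr(aggregate, "size_fraction"),
            class = c("relative_abundance_table", "data.frame"))
}

#' Write an abundance or relative-abundance table as long-format TSV
#'
#' @param table an `abundance_table` or `relative_abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  hdr <- c("# rpkm = reads per kilobase covered per million mapped reads",
           sprintf("# sample_id=%s size_fraction=%s total_mapped_reads=%s",
                   attr(table, "sample_id") %||% NA,
                   attr(table, "size_fraction") %||% NA,
                   attr(table, "total_mapped_reads") %||% NA))
  if (!is.null(attr(table, "denominator_set")))
    hdr <- c(hdr, sprintf("# percent denominator: %s",
                          attr(table, "denominator_set")))
  df <- as.data.frame(table)
  df <- cbind(sample_id = attr(table, "sample_id") %||% NA,
              size_fraction = attr(table, "size_fraction") %||% NA, df)
  write_tsv(df, path, comments = hdr)
}
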