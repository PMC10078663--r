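# Phototroph-fraction estimation: ratios of photosynthesis single-copy gene
# abundance (psbO, or chloroplast petC) over single-copy housekeeping gene
# abundance (bacterial recA; the mean of 25 ribosomal-protein genes for
# eukaryotes; the mitochondrial Rieske homologue for the petC ratio).
#
# Raw ratios can exceed 1 (psbO copy number can be 2, petC 2-3, plus
# sampling noise), so both the raw ratio and a [0,1]-clamped fraction are
# reported.

ratio_statistic <- function(numerator_gene, denominator_genes, scope,
                            raw_ratio, undefined = FALSE) {
  structure(list(numerator_gene = numerator_gene,
                 denominator_genes = denominator_genes,
                 scope = scope,
                 raw_ratio = if (undefined) NA_real_ else raw_ratio,
                 clamped_fraction = if (undefined) NA_real_
                                    else min(raw_ratio, 1),
                 undefined = undefined),
            class = "ratio_statistic")
}

#' @export
print.ratio_statistic <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("ratio_statistic [%s]: undefined (zero denominator)\n",
                x$scope))
  } else {
    cat(sprintf("ratio_statistic [%s]: %s / %s = %.4f (clamped %.4f)\n",
                x$scope, x$numerator_gene,
                paste(x$denominator_genes, collapse = ","),
                x$raw_ratio, x$clamped_fraction))
  }
  invisible(x)
}

#' Cyanobacterial fraction of the bacterioplankton (psbO / recA)
#'
#' Both psbO and recA are single-copy in bacteria, so the rpkm ratio of
#' cyanobacterial psbO over total bacterial recA estimates the fraction of
#' bacterioplankton cells that are photosynthetic.
#'
#' @param psbO_rpkm total cyanobacterial psbO rpkm.
#' @param recA_rpkm total bacterial recA rpkm.
#' @return A `ratio_statistic`; undefined-flagged when `recA_rpkm` is 0.
#' @export
phototroph_fraction_bacteria <- function(psbO_rpkm, recA_rpkm) {
  stopifnot(psbO_rpkm >= 0, recA_rpkm >= 0)
  if (recA_rpkm == 0)
    return(ratio_statistic("psbO", "recA", "whole_bacteria", NA,
                           undefined = TRUE))
  ratio_statistic("psbO", "recA", "whole_bacteria", psbO_rpkm / recA_rpkm)
}

#' Phytoplankton fraction of the eukaryotic community (psbO / ribosomal
#' proteins)
#'
#' The denominator is the arithmetic mean of the rpkm values of 25
#' single-copy ribosomal-protein genes.  `NA` entries mark genes flagged
#' absent and are excluded from the mean; zeros are genuine observations and
#' are kept.
#'
#' @param psbO_rpkm total eukaryotic psbO rpkm.
#' @param ribo_rpkms named numeric vector of per-gene ribosomal-protein rpkm
#'   values (typically rp01..rp25).
#' @return A `ratio_statistic`; undefined-flagged when the mean denominator
#'   is 0 or no gene is available.
#' @export
phototroph_fraction_eukaryotes <- function(psbO_rpkm, ribo_rpkms) {
  stopifnot(psbO_rpkm >= 0)
  genes <- names(ribo_rpkms) %||% sprintf("rp%02d", seq_along(ribo_rpkms))
  present <- !is.na(ribo_rpkms)
  if (!any(present) || mean(ribo_rpkms[present]) == 0)
    return(ratio_statistic("psbO", genes[present], "whole_eukaryotes", NA,
                           undefined = TRUE))
  ratio_statistic("psbO", genes[present], "whole_eukaryotes",
                  psbO_rpkm / mean(ribo_rpkms[present]))
}

#' Chloroplast/mitochondrial Rieske ratio
#'
#' All eukaryotic cells carry the mitochondrial Rieske homologue, while only
#' phototrophs additionally carry the chloroplast form (petC), so the rpkm
#' ratio estimates the phototroph fraction among eukaryotes.  Because petC
#' occurs at 2-3 copies per genome, the raw ratio can exceed the cell
#' fraction; both raw and clamped values are reported.
#'
#' @param chloro_petC_rpkm chloroplast Rieske (petC) rpkm.
#' @param mito_rieske_rpkm mitochondrial Rieske rpkm.
#' @return A `ratio_statistic`; undefined-flagged on zero denominator.
#' @export
rieske_ratio <- function(chloro_petC_rpkm, mito_rieske_rpkm) {
  stopifnot(chloro_petC_rpkm >= 0, mito_rieske_rpkm >= 0)
  if (mito_rieske_rpkm == 0)
    return(ratio_statistic("petC_chloroplast", "rieske_mitochondrial",
                           "whole_eukaryotes", NA, undefined = TRUE))
  ratio_statistic("petC_chloroplast", "rieske_mitochondrial",
                  "whole_eukaryotes", chloro_petC_rpkm / mito_rieske_rpkm)
}

#' Total rpkm of a gene in an abundance table, optionally restricted by group
#'
#' @param abundance a per-reference [abundance_table()].
#' @param gene gene label to sum.
#' @param groups optional group labels to restrict to.
#' @return Summed rpkm (0 when no matching reference exists).
#' @export
gene_rpkm <- function(abundance, gene, groups = NULL) {
  sel <- abundance$gene == gene
  if (!is.null(groups)) sel <- sel & abundance$group %in% groups
  sum(abundance$rpkm[sel])
}

#' Phototroph fraction within one taxon
#'
#' Restricts both numerator and denominator genes to references of the given
#' taxon (group label) before taking the ratio, e.g. the photosynthetic
#' share of dinoflagellates as psbO over the mean ribosomal-protein rpkm of
#' dinoflagellate references.
#'
#' @param abundance a per-reference [abundance_table()] covering both genes.
#' @param taxon group label to restrict to.
#' @param numerator_gene numerator gene label (default `"psbO"`).
#' @param denominator_genes denominator gene labels; their per-gene summed
#'   rpkm values are averaged (a single gene is its own mean).
#' @return A `ratio_statistic` with scope `taxon:<label>`; undefined-flagged
#'   when the taxon is absent from the denominator genes.
#' @export
fraction_by_taxon <- function(abundance, taxon, numerator_gene = "psbO",
                              denominator_genes = sprintf("rp%02d", 1:25)) {
  scope <- paste0("taxon:", taxon)
  in_taxon <- abundance$group == taxon
  den_refs <- in_taxon & abundance$gene %in% denominator_genes
  if (!any(den_refs))
    return(ratio_statistic(numerator_gene, denominator_genes, scope, NA,
                           undefined = TRUE))
  per_gene <- vapply(denominator_genes, function(g)
    sum(abundance$rpkm[in_taxon & abundance$gene == g]), numeric(1))
  # only genes with at least one reference in the taxon enter the mean
  has_ref <- vapply(denominator_genes, function(g)
    any(in_taxon & abundance$gene == g), logical(1))
  den <- mean(per_gene[has_ref])
  if (den == 0)
    return(ratio_statistic(numerator_gene, denominator_genes[has_ref],
                           scope, NA, undefined = TRUE))
  num <- sum(abundance$rpkm[in_taxon & abundance$gene == numerator_gene])
  ratio_statistic(numerator_gene, denominator_genes[has_ref], scope,
                  num / den)
}

#' Write ratio statistics as TSV
#'
#' @param ratios a list of `ratio_statistic` objects.
#' @param path output path.
#' @param sample_id,size_fraction sample annotation columns.
#' @return `path`, invisibly.
#' @export
write_ratio_tsv <- function(ratios, path, sample_id = "sample1",
                            size_fraction = "0.2-3") {
  if (inherits(ratios, "ratio_statistic")) ratios <- list(ratios)
  df <- do.call(rbind, lapply(ratios, function(r)
    data.frame(sample_id = sample_id, size_fraction = size_fraction,
               scope = r$scope, numerator_gene = r$numerator_gene,
               denominator_genes = paste(r$denominator_genes, collapse = ","),
               raw_ratio = r$raw_ratio,
               clamped_fraction = r$clamped_fraction,
               flags = if (r$undefined) "undefined" else "",
               stringsAsFactors = FALSE)))
  write_tsv(df, path,
            comments = c("# phototroph-fraction ratio statistics",
                         "# raw_ratio = numerator rpkm / denominator rpkm;",
                         "# clamped_fraction = min(raw_ratio, 1)"))
}
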