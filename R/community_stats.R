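# Community ecology statistics: Shannon diversity, Spearman correlation
# (exact permutation p for small n), genetic distances with a barcoding-gap
# report, and optical biovolume computations.

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * ln p_i)` over taxa with positive abundance, with
#' `p_i = a_i / sum(a)`.
#'
#' @param abundances nonnegative numeric vector with at least one positive
#'   entry.
#' @return H (numeric scalar).
#' @export
shannon <- function(abundances) {
  if (any(!is.finite(abundances)) || any(abundances < 0))
    stop("abundances must be finite and nonnegative", call. = FALSE)
  total <- sum(abundances)
  if (total <= 0) stop("all abundances are zero", call. = FALSE)
  p <- abundances[abundances > 0] / total
  -sum(p * log(p))
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(rep.int(i, nrow(p)), p + (p >= i))))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Ties receive average ranks; rho is the Pearson correlation of the ranks.
#' For `n <= 9` the two-sided p-value is computed by full enumeration of all
#' n! permutations of one vector (exact even with ties); for larger n the
#' t approximation `t = rho * sqrt((n-2) / (1-rho^2))` is used.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param exact_max largest n for which the exact permutation p is computed.
#' @return A list with `rho`, `p_value`, `method` and `undefined` (TRUE when
#'   either vector is constant, in which case `rho` is NA).
#' @export
spearman_rho <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length", call. = FALSE)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, method = "none",
                undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_all(n)
    ryc <- ry - mean(ry); rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector((matrix(ryc[perms], nrow(perms), n) %*% rxc) /
                            denom)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p_value = p, method = method, undefined = FALSE)
}

#' Pairwise genetic distances with a barcoding-gap report
#'
#' Distances are computed under `"p_distance"`, `"K2P"` or `"TN93"` (the
#' default; the closest standard stand-in for composite-likelihood
#' estimators) with pairwise deletion of gap/N columns.  The report
#' partitions pairs into intraspecific and interspecific sets, gives each
#' species its local barcoding gap (max intraspecific vs min interspecific
#' distance) and tests the global gap (min interspecific over all pairs
#' greater than max intraspecific over all pairs).
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal length, gaps `-`).
#' @param species character vector (parallel to `seqs`) of species labels.
#' @param model distance model.
#' @param min_shared minimum pairwise shared (ungapped, unambiguous)
#'   columns; fewer is an error.
#' @return A list of class `distance_summary` with `distances` (matrix),
#'   `pairs` (long data.frame), `intraspecific`, `interspecific` (numeric
#'   vectors), `per_species` (local-gap table) and `global_gap`.
#' @export
genetic_distances <- function(seqs, species,
                              model = c("TN93", "K2P", "p_distance"),
                              min_shared = 50L) {
  model <- match.arg(model)
  stopifnot(length(seqs) == length(species), length(seqs) >= 2L)
  if (length(unique(species)) < 2L)
    stop("need at least 2 species", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length", call. = FALSE)
  ids <- names(seqs) %||% sprintf("seq%03d", seq_along(seqs))
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- ids
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  # pairwise shared-column check
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (sum(good[i, ] & good[j, ]) < min_shared)
      stopf("sequences '%s' and '%s' share fewer than %d columns",
            ids[i], ids[j], min_shared)
  }
  dna <- ape::as.DNAbin(m)
  ape_model <- switch(model, p_distance = "raw", K2P = "K80", TN93 = "TN93")
  d <- as.matrix(ape::dist.dna(dna, model = ape_model,
                               pairwise.deletion = TRUE))
  singletons <- names(which(table(species) == 1L))
  if (length(singletons) > 0L)
    warning("species with a single sequence excluded from the ",
            "intraspecific set: ", paste(singletons, collapse = ", "),
            call. = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(n - 1L), function(i)
    data.frame(id1 = ids[i], id2 = ids[seq.int(i + 1L, n)],
               species1 = species[i], species2 = species[seq.int(i + 1L, n)],
               distance = d[i, seq.int(i + 1L, n)],
               stringsAsFactors = FALSE)))
  rownames(pairs) <- NULL
  pairs$type <- ifelse(pairs$species1 == pairs$species2,
                       "intraspecific", "interspecific")
  intra <- pairs$distance[pairs$type == "intraspecific"]
  inter <- pairs$distance[pairs$type == "interspecific"]
  per_species <- do.call(rbind, lapply(sort_c(unique(species)), function(sp) {
    ii <- pairs$type == "intraspecific" & pairs$species1 == sp
    jj <- pairs$type == "interspecific" &
      (pairs$species1 == sp | pairs$species2 == sp)
    data.frame(species = sp,
               max_intraspecific = if (any(ii)) max(pairs$distance[ii])
                                   else NA_real_,
               min_interspecific = if (any(jj)) min(pairs$distance[jj])
                                   else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_species$local_gap <- per_species$min_interspecific >
    per_species$max_intraspecific
  global_gap <- list(
    max_intraspecific = if (length(intra)) max(intra) else NA_real_,
    min_interspecific = if (length(inter)) min(inter) else NA_real_,
    gap = length(intra) > 0L && length(inter) > 0L &&
      min(inter) > max(intra))
  structure(list(model = model, distances = d, pairs = pairs,
                 intraspecific = intra, interspecific = inter,
                 per_species = per_species, global_gap = global_gap),
            class = "distance_summary")
}

#' Spherical cell biovolume from flow-cytometry side scatter
#'
#' Cell diameter is estimated from bead-standardized side scatter through a
#' power law `d = a * ssc^b`, and the cell is treated as a sphere:
#' `V = (pi/6) d^3`.  The power-law coefficients are instrument
#' calibrations and must be supplied explicitly; there are no defaults.
#'
#' @param ssc positive side-scatter value(s), bead-standardized (unitless).
#' @param coeffs list or named vector with `a` and `b`.
#' @return Cell volume(s) in cubic micrometres.
#' @export
sphere_biovolume_from_ssc <- function(ssc, coeffs) {
  if (any(!is.finite(ssc)) || any(ssc <= 0))
    stop("ssc must be positive", call. = FALSE)
  a <- coeffs[["a"]]; b <- coeffs[["b"]]
  if (is.null(a) || is.null(b))
    stop("coeffs must supply both a and b", call. = FALSE)
  d <- a * ssc^b
  (pi / 6) * d^3
}

#' Ellipsoidal cell biovolume from image axes
#'
#' Prolate-spheroid volume from the major and minor axes of a cell image:
#' `V = (pi/6) * major * minor^2` (the minor axis is used for both short
#' axes).  Equal axes reduce to the sphere volume.
#'
#' @param major,minor axes in micrometres; `major >= minor > 0`.
#' @return Cell volume(s) in cubic micrometres.
#' @export
ellipsoid_biovolume <- function(major, minor) {
  if (any(!is.finite(major)) || any(!is.finite(minor)) || any(minor <= 0))
    stop("axes must be positive", call. = FALSE)
  if (any(major < minor))
    stop("major axis must be >= minor axis", call. = FALSE)
  (pi / 6) * major * minor^2
}

#' Relative biovolume per taxon from an optical count table
#'
#' Taxon biovolume is `sum(cell_count * per-cell volume)`; per-cell volumes
#' come from side scatter (`ssc` column; requires `ssc_coeffs`) or from image
#' axes (`major_axis`, `minor_axis`).  Mixing both geometry types in one
#' table is an error unless `allow_mixed = TRUE`.
#'
#' @param records data.frame with `taxon`, `cell_count` and either `ssc` or
#'   `major_axis`/`minor_axis`.
#' @param ssc_coeffs power-law coefficients for [sphere_biovolume_from_ssc()].
#' @param allow_mixed allow tables mixing ssc- and axis-based rows.
#' @return data.frame with `taxon`, `biovolume` (um^3) and `percent`
#'   (sums to 100).
#' @export
relative_biovolume <- function(records, ssc_coeffs = NULL,
                               allow_mixed = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("taxon", "cell_count") %in% names(records)))
  has_ssc <- "ssc" %in% names(records) && any(!is.na(records$ssc))
  has_axes <- all(c("major_axis", "minor_axis") %in% names(records)) &&
    any(!is.na(records$major_axis))
  if (has_ssc && has_axes && !allow_mixed)
    stop("table mixes ssc and axis geometries; set allow_mixed = TRUE ",
         "to combine them", call. = FALSE)
  vol <- rep(NA_real_, nrow(records))
  if (has_ssc) {
    i <- !is.na(records$ssc)
    vol[i] <- sphere_biovolume_from_ssc(records$ssc[i], ssc_coeffs)
  }
  if (has_axes) {
    i <- is.na(vol) & !is.na(records$major_axis)
    vol[i] <- ellipsoid_biovolume(records$major_axis[i],
                                  records$minor_axis[i])
  }
  if (any(is.na(vol)))
    stop("some records have no resolvable per-cell volume", call. = FALSE)
  bio <- tapply(records$cell_count * vol, records$taxon, sum)
  out <- data.frame(taxon = names(bio), biovolume = as.numeric(bio),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$biovolume / sum(out$biovolume)
  out[order_c(out$taxon), , drop = FALSE]
}
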