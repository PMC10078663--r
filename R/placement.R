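# Placement-based taxonomy for environmental psbO fragments: best-frame
# translation, profile alignment onto a fixed reference alignment, distance
# placement on a support-annotated reference tree, and the monophyly +
# support classification rule (a query is assigned the group label of the
# first ancestral clade that has statistical support strictly above the
# threshold and contains references of a single group).

#' Construct a reference alignment
#'
#' @param rows named character vector of equal-length aligned amino-acid
#'   rows (gaps `-`); names are reference ids.
#' @return Object of class `reference_alignment`.
#' @export
reference_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  if (anyDuplicated(names(rows)))
    stop("duplicate row ids in alignment", call. = FALSE)
  structure(list(rows = rows, width = w), class = "reference_alignment")
}

#' Read an aligned FASTA of amino-acid reference rows
#'
#' @param path aligned FASTA path.
#' @return A [reference_alignment()].
#' @export
read_reference_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  rows <- as.character(x)
  names(rows) <- vapply(strsplit(names(x), "[ \t]"), `[`, character(1), 1L)
  reference_alignment(rows)
}

#' Construct a support-annotated reference tree
#'
#' Internal node labels of the `phylo` object are interpreted as support
#' values in `[0, 1]`.  Unrooted trees are midpoint-rooted (and a message is
#' emitted), since the classification walk needs a root.
#'
#' @param tree an `ape::phylo` object (or path to a newick file).
#' @param tip_groups named character vector mapping tip labels to group
#'   labels.
#' @return Object of class `reference_tree` with elements `tree`, `supports`
#'   (numeric per internal node) and `tip_groups`.
#' @export
reference_tree <- function(tree, tip_groups) {
  if (is.character(tree) && length(tree) == 1L) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    message("unrooted input tree: applying midpoint rooting")
    tree <- phangorn::midpoint(tree)
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_groups))
  if (length(missing_tips) > 0L)
    stopf("no group label for tip '%s'", missing_tips[1])
  supports <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    supports <- suppressWarnings(as.numeric(tree$node.label))
  }
  if (any(supports < 0 | supports > 1, na.rm = TRUE))
    stop("support values must lie in [0, 1]", call. = FALSE)
  structure(list(tree = tree, supports = supports,
                 tip_groups = tip_groups[tree$tip.label]),
            class = "reference_tree")
}

# substitution matrix accessor (standard amino-acid log-odds matrix)
aa_submat <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

translate_frame <- function(nt, frame) {
  s <- if (frame > 0) nt else as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  off <- abs(frame) - 1L
  len <- nchar(s) - off
  len <- len - (len %% 3L)
  if (len < 3L) return("")
  sub <- Biostrings::DNAString(substr(s, off + 1L, off + len))
  suppressWarnings(as.character(
    Biostrings::translate(sub, if.fuzzy.codon = "X")))
}

#' Choose the reading frame that best matches a reference profile
#'
#' Translates all six frames (standard genetic code; internal stops are
#' allowed and scored) and returns the frame whose translation attains the
#' highest local alignment score against the profile consensus under the
#' chosen substitution matrix.  Ties go to the lowest frame in the order
#' +1, +2, +3, -1, -2, -3.
#'
#' @param nt nucleotide sequence (>= 60 nt).
#' @param profile a [reference_alignment()].
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @return A list with `frame`, `aa` (the translation), `score`; or
#'   `frame = NA` with `reason = "untranslatable"` when all frames score
#'   <= 0.
#' @export
best_frame_translate <- function(nt, profile, matrix = "BLOSUM62") {
  stopifnot(inherits(profile, "reference_alignment"))
  nt <- clean_nucleotides(nt, "query")
  if (nchar(nt) < 60L) stop("query shorter than 60 nt", call. = FALSE)
  cons <- profile_consensus(profile)
  sm <- aa_submat(matrix)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  best <- NULL
  for (f in frames) {
    aa <- translate_frame(nt, f)
    if (!nzchar(aa)) next
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), Biostrings::AAString(cons), type = "local",
      substitutionMatrix = sm, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    if (is.null(best) || sc > best$score)
      best <- list(frame = f, aa = aa, score = sc)
  }
  if (is.null(best) || best$score <= 0)
    return(list(frame = NA_integer_, aa = NA_character_,
                score = if (is.null(best)) -Inf else best$score,
                reason = "untranslatable"))
  best
}

# per-column consensus: most frequent non-gap residue, alphabetical ties
profile_consensus <- function(profile) {
  m <- do.call(rbind, strsplit(unname(profile$rows), ""))
  paste(apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("X")
    tab <- table(col)
    sort_c(names(tab)[tab == max(tab)])[1]
  }), collapse = "")
}

#' Align an amino-acid fragment onto the fixed columns of a reference
#' alignment
#'
#' Position-specific scores are the mean substitution score of the query
#' residue against the (non-gap) residues of each profile column.  Query
#' residues are assigned to strictly increasing columns; internal column
#' skips are penalized with affine gap costs and terminal skips are free.
#' Reference columns are never altered (add-to-alignment contract), so
#' query insertions relative to the profile are not representable and the
#' closest column path is chosen instead.
#'
#' @param aa amino-acid fragment (>= 20 residues).
#' @param ref_aln a [reference_alignment()].
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine penalties for internal column skips
#'   (negative scores).
#' @return A list with `aligned` (query row padded to the profile width),
#'   `columns` (1-based column of each query residue), `score` and
#'   `low_confidence` (TRUE when the profile score is <= 0).
#' @export
align_to_profile <- function(aa, ref_aln, matrix = "BLOSUM62",
                             gap_open = -10, gap_extend = -1) {
  stopifnot(inherits(ref_aln, "reference_alignment"))
  aa <- toupper(aa)
  if (nchar(aa) < 20L) stop("fragment shorter than 20 aa", call. = FALSE)
  if (nchar(aa) > 2L * ref_aln$width)
    stop("fragment longer than twice the profile width", call. = FALSE)
  sm <- aa_submat(matrix)
  qres <- strsplit(aa, "")[[1]]
  qres[!qres %in% rownames(sm)] <- "X"
  pm <- do.call(rbind, strsplit(unname(ref_aln$rows), ""))
  colscore <- matrix(0, nrow = length(qres), ncol = ref_aln$width)
  for (j in seq_len(ref_aln$width)) {
    col <- pm[, j]
    col <- col[col != "-"]
    col[!col %in% colnames(sm)] <- "X"
    colscore[, j] <- if (length(col) == 0L) -4
      else rowMeans(sm[qres, col, drop = FALSE])
  }
  res <- .profile_align_cpp(colscore, gap_open, gap_extend)
  if (!is.finite(res$score))
    stop("fragment could not be mapped onto the profile", call. = FALSE)
  aligned <- rep("-", ref_aln$width)
  aligned[res$columns] <- qres
  list(aligned = paste(aligned, collapse = ""), columns = res$columns,
       score = res$score, low_confidence = res$score <= 0)
}

#' Place an aligned query on a reference tree by minimum corrected distance
#'
#' The distance to every reference is the mismatch proportion over shared
#' ungapped alignment columns, Poisson-corrected as `d = -ln(1 - p)`.  The
#' query attaches to the pendant edge of the minimum-distance reference
#' (ties: smallest reference id).  References sharing fewer than 20 ungapped
#' columns with the query are skipped; if none remains the query is
#' unplaceable.
#'
#' @param aligned_query query row from [align_to_profile()] (string of the
#'   profile width).
#' @param ref_aln a [reference_alignment()].
#' @param tree a [reference_tree()] whose tips are alignment row ids.
#' @param query_id identifier carried into the result.
#' @return A list of class `query_placement` with `query_id`,
#'   `attachment_edge` (tip label whose pendant edge the query attaches to),
#'   `nearest_reference_id`, `distance`, `shared_columns`; or a list with
#'   `unplaceable = TRUE`.
#' @export
place_query <- function(aligned_query, ref_aln, tree, query_id = "query") {
  stopifnot(inherits(ref_aln, "reference_alignment"),
            inherits(tree, "reference_tree"))
  if (is.list(aligned_query)) aligned_query <- aligned_query$aligned
  q <- strsplit(toupper(aligned_query), "")[[1]]
  if (length(q) != ref_aln$width)
    stop("aligned query width does not match the profile", call. = FALSE)
  ids <- sort_c(intersect(tree$tree$tip.label, names(ref_aln$rows)))
  best <- NULL
  for (id in ids) {
    r <- strsplit(ref_aln$rows[[id]], "")[[1]]
    shared <- which(q != "-" & r != "-")
    if (length(shared) < 20L) next
    p <- mean(q[shared] != r[shared])
    d <- if (p >= 1) Inf else -log(1 - p)
    if (is.null(best) || d < best$distance)
      best <- list(query_id = query_id, attachment_edge = id,
                   nearest_reference_id = id, distance = d,
                   shared_columns = length(shared))
  }
  if (is.null(best))
    return(list(query_id = query_id, unplaceable = TRUE))
  best$unplaceable <- FALSE
  class(best) <- "query_placement"
  best
}

# parent lookup in an ape phylo object
phylo_parent <- function(tree, node) {
  i <- match(node, tree$edge[, 2])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1]
}

phylo_tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phylo_tips_under, tree = tree))
}

#' Classify a placement by the monophyly + support rule
#'
#' Walks rootward from the attachment edge; at each internal node whose
#' support is strictly greater than `support_threshold` and whose tip set
#' carries exactly one group label, that label is returned.  If no such node
#' exists up to the root the query is `"unclassified"`.  Support exactly at
#' the threshold never classifies, and nodes without a support value are
#' skipped.
#'
#' @param tree a [reference_tree()].
#' @param placement a [place_query()] result, or a tip/node identifier
#'   naming the attachment edge (the edge above that tip or internal node).
#' @param support_threshold minimum (exclusive) support; default 0.7.
#' @return A group label, or `"unclassified"`.
#' @export
classify_placement <- function(tree, placement, support_threshold = 0.7) {
  stopifnot(inherits(tree, "reference_tree"))
  node <- if (is.list(placement)) {
    if (isTRUE(placement$unplaceable)) return("unclassified")
    placement$attachment_edge
  } else placement
  phy <- tree$tree
  ntip <- length(phy$tip.label)
  if (is.character(node)) {
    node <- match(node, phy$tip.label)
    if (is.na(node)) stop("unknown attachment tip", call. = FALSE)
  }
  root <- ntip + 1L
  while (!is.na(node)) {
    if (node > ntip) { # internal node: check support + group purity
      supp <- tree$supports[node - ntip]
      if (!is.na(supp) && supp > support_threshold) {
        groups <- unique(tree$tip_groups[phylo_tips_under(phy, node)])
        if (length(groups) == 1L) return(unname(groups))
      }
    }
    if (node == root) break
    node <- phylo_parent(phy, node)
  }
  "unclassified"
}

#' End-to-end taxonomic classification of nucleotide psbO fragments
#'
#' Convenience wrapper: best-frame translation, profile alignment, distance
#' placement and support-based classification for a set of fragments.
#'
#' @param queries named character vector of nucleotide fragments.
#' @param ref_aln a [reference_alignment()].
#' @param tree a [reference_tree()].
#' @param support_threshold classification support threshold.
#' @param matrix substitution matrix name.
#' @return data.frame with `query_id`, `frame`, `nearest_reference`,
#'   `distance`, `assigned_group`.
#' @export
classify_fragments <- function(queries, ref_aln, tree,
                               support_threshold = 0.7,
                               matrix = "BLOSUM62") {
  queries <- as_read_vector(queries)
  out <- lapply(names(queries), function(id) {
    tr <- best_frame_translate(queries[[id]], ref_aln, matrix)
    if (is.na(tr$frame))
      return(data.frame(query_id = id, frame = NA_integer_,
                        nearest_reference = NA_character_,
                        distance = NA_real_,
                        assigned_group = "unclassified",
                        stringsAsFactors = FALSE))
    al <- align_to_profile(tr$aa, ref_aln, matrix)
    pl <- place_query(al$aligned, ref_aln, tree, query_id = id)
    if (isTRUE(pl$unplaceable))
      return(data.frame(query_id = id, frame = tr$frame,
                        nearest_reference = NA_character_,
                        distance = NA_real_,
                        assigned_group = "unclassified",
                        stringsAsFactors = FALSE))
    data.frame(query_id = id, frame = tr$frame,
               nearest_reference = pl$nearest_reference_id,
               distance = pl$distance,
               assigned_group = classify_placement(tree, pl,
                                                   support_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
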