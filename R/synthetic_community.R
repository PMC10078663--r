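# Mock-community simulator: reference sets evolved on group-coherent
# coalescent trees, shotgun reads drawn in proportion to cell abundance x
# gene copy number x gene length, and optical count tables -- all with known
# ground truth, so that every pipeline stage (and the rRNA copy-number bias
# mechanism) is testable without external data.

#' Default simulated marker gene lengths (bp)
#'
#' psbO uses the average conserved coding-region length of marine psbO
#' sequences (~473 bp, rounded to a codon multiple); the other genes use
#' typical lengths for bacterial recA, ribosomal-protein CDS, Rieske
#' subunits and SSU rRNA genes.
#'
#' @return Named integer vector of gene lengths.
#' @export
marker_gene_lengths <- function() {
  c(psbO = 474L, recA = 1068L,
    setNames(rep(450L, 25), sprintf("rp%02d", 1:25)),
    petC_chloroplast = 501L, rieske_mitochondrial = 501L,
    rRNA_16S = 1500L, rRNA_18S = 1797L)
}

validate_taxon_spec <- function(spec) {
  needed <- c("name", "group", "domain", "photosynthetic", "fraction",
              "psbO_copies", "recA_copies", "rp_copies", "rRNA_copies",
              "petC_copies", "rieske_copies")
  miss <- setdiff(needed, names(spec))
  if (length(miss) > 0L)
    stopf("taxon spec is missing columns: %s", paste(miss, collapse = ", "))
  if (abs(sum(spec$fraction) - 1) > 1e-8)
    stop("cell fractions must sum to 1", call. = FALSE)
  if (any(spec$fraction < 0)) stop("negative cell fraction", call. = FALSE)
  if (!all(spec$domain %in% c("bacteria", "eukaryote")))
    stop("domain must be 'bacteria' or 'eukaryote'", call. = FALSE)
  if (!all(spec$group %in% plankton_groups()))
    stopf("unknown group label '%s'",
          setdiff(spec$group, plankton_groups())[1])
  if (any(!spec$photosynthetic & spec$psbO_copies > 0))
    stop("non-photosynthetic taxa cannot carry psbO", call. = FALSE)
  if (any(spec$psbO_copies > 2))
    stop("psbO copy number is at most 2 per genome", call. = FALSE)
  if (anyDuplicated(spec$name)) stop("duplicate taxon names", call. = FALSE)
  invisible(spec)
}

# per-taxon copy number for a concrete gene label
copies_for_gene <- function(spec, gene) {
  if (gene == "psbO") return(spec$psbO_copies)
  if (gene == "recA") return(ifelse(spec$domain == "bacteria",
                                    spec$recA_copies, 0L))
  if (grepl("^rp[0-9]+$", gene)) return(ifelse(spec$domain == "eukaryote",
                                               spec$rp_copies, 0L))
  if (gene == "rRNA_16S") return(ifelse(spec$domain == "bacteria",
                                        spec$rRNA_copies, 0L))
  if (gene == "rRNA_18S") return(ifelse(spec$domain == "eukaryote",
                                        spec$rRNA_copies, 0L))
  if (gene == "petC_chloroplast")
    return(ifelse(spec$domain == "eukaryote" & spec$photosynthetic,
                  spec$petC_copies, 0L))
  if (gene == "rieske_mitochondrial")
    return(ifelse(spec$domain == "eukaryote", spec$rieske_copies, 0L))
  stopf("unknown gene '%s'", gene)
}

#' The default six-taxon mock phytoplankton community
#'
#' Two picocyanobacteria (Prochlorococcus, Synechococcus) and four
#' eukaryotic phytoplankton groups with realistic relative cell abundances
#' (cyanobacteria numerically dominant, dinoflagellates rare), single-copy
#' psbO/recA/ribosomal proteins, petC at 2 copies, and rRNA gene copy
#' numbers spanning the documented range from ~1 in picocyanobacteria and
#' small chlorophytes to hundreds-thousands in diatoms and dinoflagellates.
#'
#' @return data.frame taxon specification (one row per taxon).
#' @export
mock_community <- function() {
  spec <- data.frame(
    name = c("Prochlorococcus_A", "Synechococcus_A", "Chlorophyte_A",
             "Haptophyte_A", "Diatom_A", "Dinoflagellate_A"),
    group = c("Prochlorococcus", "Synechococcus", "chlorophytes",
              "haptophytes", "diatoms", "dinoflagellates"),
    domain = c("bacteria", "bacteria", "eukaryote", "eukaryote",
               "eukaryote", "eukaryote"),
    photosynthetic = TRUE,
    fraction = c(0.30, 0.10, 0.25, 0.15, 0.15, 0.05),
    psbO_copies = 1L, recA_copies = 1L, rp_copies = 1L,
    rRNA_copies = c(1L, 2L, 4L, 30L, 150L, 1000L),
    petC_copies = 2L, rieske_copies = 1L,
    stringsAsFactors = FALSE)
  validate_taxon_spec(spec)
}

#' A mock bacterioplankton community with a given phototroph fraction
#'
#' Two cyanobacteria (Prochlorococcus twice as abundant as Synechococcus)
#' share `phototroph_fraction` of the cells; four heterotrophic bacterial
#' taxa share the rest equally.  All bacterial genomes carry single-copy
#' recA; only the cyanobacteria carry psbO.
#'
#' @param phototroph_fraction fraction of cells that are cyanobacteria.
#' @return data.frame taxon specification.
#' @export
bacterio_community <- function(phototroph_fraction = 0.15) {
  stopifnot(phototroph_fraction >= 0, phototroph_fraction < 1)
  f <- phototroph_fraction
  spec <- data.frame(
    name = c("Prochlorococcus_B", "Synechococcus_B",
             sprintf("Heterotroph_%s", LETTERS[1:4])),
    group = c("Prochlorococcus", "Synechococcus",
              rep("heterotrophic_bacteria", 4)),
    domain = "bacteria",
    photosynthetic = c(TRUE, TRUE, rep(FALSE, 4)),
    fraction = c(2 * f / 3, f / 3, rep((1 - f) / 4, 4)),
    psbO_copies = c(1L, 1L, rep(0L, 4)),
    recA_copies = 1L, rp_copies = 0L,
    rRNA_copies = c(1L, 2L, rep(2L, 4)),
    petC_copies = 0L, rieske_copies = 0L,
    stringsAsFactors = FALSE)
  validate_taxon_spec(spec)
}

#' A random phytoplankton community
#'
#' Cell fractions are drawn from a symmetric Dirichlet; groups are assigned
#' round-robin over the photosynthetic groups; all genomes carry single-copy
#' psbO (so that psbO profiles estimate cell fractions directly) and rRNA
#' copy numbers drawn log-uniformly between 1 and 1000.
#'
#' @param n_taxa number of taxa.
#' @param seed RNG seed.
#' @param alpha Dirichlet concentration (1 = uniform on the simplex).
#' @return data.frame taxon specification.
#' @export
random_community <- function(n_taxa = 6L, seed = NULL, alpha = 1) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(n_taxa, shape = alpha)
  groups <- rep(c("chlorophytes", "haptophytes", "diatoms",
                  "dinoflagellates", "pelagophytes"),
                length.out = n_taxa)
  spec <- data.frame(
    name = sprintf("Taxon_%02d", seq_len(n_taxa)),
    group = groups, domain = "eukaryote", photosynthetic = TRUE,
    fraction = g / sum(g),
    psbO_copies = 1L, recA_copies = 0L, rp_copies = 1L,
    rRNA_copies = as.integer(round(10^runif(n_taxa, 0, 3))),
    petC_copies = 2L, rieske_copies = 1L,
    stringsAsFactors = FALSE)
  validate_taxon_spec(spec)
}

# random ancestral coding sequence (no stop codons in frame +1)
random_coding_sequence <- function(length_bp) {
  stopifnot(length_bp %% 3L == 0L)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, length_bp / 3L, replace = TRUE), collapse = "")
}

random_nt_sequence <- function(length_bp) {
  paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
        collapse = "")
}

# group-coherent random tree: a coalescent backbone over groups whose tips
# are replaced by per-group coalescent subtrees, so taxa of a group are
# always monophyletic (group labels are clades, as in a curated marker
# phylogeny)
group_coherent_tree <- function(spec) {
  groups <- unique(spec$group)
  k <- length(groups)
  sub_newick <- function(taxa) {
    if (length(taxa) == 1L) return(taxa)
    s <- ape::write.tree(ape::rcoal(length(taxa), tip.label = taxa))
    sub(";$", "", s)
  }
  if (k == 1L) {
    nwk <- paste0(sub_newick(spec$name), ";")
    if (length(spec$name) == 1L)
      nwk <- paste0("(", spec$name, ":1);")
    return(ape::read.tree(text = nwk))
  }
  ph <- sprintf("ZZGRP%dZZ", seq_len(k))
  bb <- ape::rcoal(k, tip.label = ph)
  nwk <- ape::write.tree(bb)
  for (i in seq_len(k)) {
    taxa <- spec$name[spec$group == groups[i]]
    nwk <- sub(ph[i], sub_newick(taxa), nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}

# Scale tree edges so the mean pairwise path length equals the Jukes-Cantor
# distance corresponding to the requested mean observed divergence, then
# enforce a separation floor: every pairwise distance must be at least one
# third of the mean.  Reference databases catalogue distinguishable taxa;
# without the floor, occasional coalescent draws make two taxa nearly
# identical, and read recruitment against such a database is ill-posed at
# any read length.  The floor is imposed by extending all tip branches by a
# common amount (which raises every pairwise distance equally) and rescaling
# back to the target mean.
scale_tree_to_divergence <- function(tree, divergence) {
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)", call. = FALSE)
  if (length(tree$tip.label) < 2L) return(tree)
  if (divergence == 0) {
    tree$edge.length <- rep(0, length(tree$edge.length))
    return(tree)
  }
  target <- -0.75 * log(1 - 4 * divergence / 3)
  d <- ape::cophenetic.phylo(tree)
  dv <- d[upper.tri(d)]
  m <- mean(dv); dmin <- min(dv)
  if (m <= 0) stop("degenerate zero-length tree", call. = FALSE)
  delta <- max(0, (m - 3 * dmin) / 4) # so (dmin + 2d) >= (m + 2d) / 3
  is_tip <- tree$edge[, 2] <= length(tree$tip.label)
  tree$edge.length[is_tip] <- tree$edge.length[is_tip] + delta
  tree$edge.length <- tree$edge.length * target / (m + 2 * delta)
  tree
}

#' Simulate per-gene marker reference sets for a community
#'
#' A random ancestral sequence per gene (codon-sampled without stops for
#' protein-coding genes) evolves under Jukes-Cantor down a group-coherent
#' coalescent tree scaled so the mean pairwise observed divergence matches
#' `divergence`.  Tip branches are extended so the minimum pairwise
#' divergence is at least one third of the mean: a marker database
#' catalogues distinguishable taxa, and quantification against
#' near-identical references is ill-posed at any read length.  Emits one [reference_db()] per gene (restricted to the
#' taxa carrying the gene), the psbO reference tree with supports, and the
#' true psbO protein alignment (frame +1 translations; ungapped).
#'
#' @param spec taxon specification (see [mock_community()]).
#' @param divergence target mean pairwise observed nucleotide divergence,
#'   in `[0, 0.5)`; 0 makes all references identical to the ancestor.
#' @param seed RNG seed.
#' @param genes gene labels to simulate (default psbO + recA + the
#'   domain-appropriate rRNA genes).
#' @param gene_lengths named vector overriding [marker_gene_lengths()].
#' @param supports support value(s) written on internal nodes of the psbO
#'   tree (recycled; default 1.0, degradable for testing the
#'   classification rule).
#' @return List with `databases` (named list of `reference_db`), `tree`
#'   (a [reference_tree()] over psbO reference ids, or NULL), `alignment`
#'   (a [reference_alignment()] of PsbO proteins, or NULL) and `taxon_tree`
#'   (the scaled `phylo` over taxa).
#' @export
simulate_reference_set <- function(spec, divergence = 0.15, seed = NULL,
                                   genes = c("psbO", "recA", "rRNA_16S",
                                             "rRNA_18S"),
                                   gene_lengths = marker_gene_lengths(),
                                   supports = 1.0) {
  validate_taxon_spec(spec)
  if (nrow(spec) < 2L || nrow(spec) > 200L)
    stop("between 2 and 200 taxa are supported", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lens <- gene_lengths
  if (divergence > 0 && any(divergence * lens[genes] < 1))
    stop("divergence too small for the gene length (expected differences ",
         "< 1)", call. = FALSE)
  tree <- scale_tree_to_divergence(group_coherent_tree(spec), divergence)

  dbs <- list()
  psbo_db <- NULL
  for (gene in genes) {
    copies <- copies_for_gene(spec, gene)
    taxa <- spec$name[copies > 0]
    if (length(taxa) == 0L) next
    len <- unname(lens[[gene]])
    coding <- !gene %in% c("rRNA_16S", "rRNA_18S")
    anc <- if (coding) random_coding_sequence(len - len %% 3L)
           else random_nt_sequence(len)
    sub_tree <- if (length(taxa) < length(tree$tip.label))
      ape::keep.tip(tree, taxa) else tree
    tips <- if (length(taxa) == 1L) {
      setNames(anc, taxa) # single carrier: the ancestral sequence itself
    } else {
      sim <- phangorn::simSeq(sub_tree, l = nchar(anc),
                              rootseq = strsplit(tolower(anc), "")[[1]],
                              type = "DNA")
      mat <- toupper(as.character(sim))
      setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
    }
    idx <- match(names(tips), spec$name)
    rec <- data.frame(
      record_id = paste0(names(tips), "_", gene),
      gene = gene,
      group = spec$group[idx],
      taxonomy = paste(ifelse(spec$domain[idx] == "bacteria", "Bacteria",
                              "Eukaryota"),
                       spec$group[idx], names(tips), sep = ";"),
      sequence = unname(tips), stringsAsFactors = FALSE)
    dbs[[gene]] <- reference_db(rec, gene = gene,
                                provenance = "simulated community")
    if (gene == "psbO") psbo_db <- list(taxa = names(tips), tree = sub_tree)
  }

  ref_tree <- NULL; aln <- NULL
  if (!is.null(psbo_db) && length(psbo_db$taxa) >= 2L) {
    pt <- psbo_db$tree
    pt$tip.label <- paste0(pt$tip.label, "_psbO")
    pt$node.label <- format(rep_len(supports, pt$Nnode), trim = TRUE)
    tip_groups <- setNames(
      dbs$psbO$records$group[match(pt$tip.label,
                                   dbs$psbO$records$record_id)],
      pt$tip.label)
    ref_tree <- reference_tree(pt, tip_groups)
    aln <- reference_alignment(setNames(
      vapply(dbs$psbO$records$sequence, translate_frame, character(1),
             frame = 1L, USE.NAMES = FALSE),
      dbs$psbO$records$record_id))
  }
  list(databases = dbs, tree = ref_tree, alignment = aln,
       taxon_tree = tree)
}

#' Simulate shotgun reads from a community with known provenance
#'
#' Reads are drawn multinomially over (taxon, gene) pairs with probability
#' proportional to cell fraction x gene copy number x gene length --- the
#' abundance model under which single-copy markers track cell abundance and
#' multi-copy rRNA genes overrepresent high-copy taxa.  Start positions are
#' uniform, substitution errors occur per base at `error_rate`, and half of
#' the reads are reverse-complemented.
#'
#' @param spec taxon specification.
#' @param refs output of [simulate_reference_set()] (or its `databases`
#'   element).
#' @param n_reads total number of reads.
#' @param read_length read length in bp (must not exceed the shortest
#'   simulated gene).
#' @param error_rate per-base substitution error rate (< 0.1; indels are
#'   not simulated).
#' @param seed RNG seed.
#' @param rrna_amplification optional named per-taxon multiplicative factor
#'   on rRNA read probability (PCR-style amplification bias; default off).
#' @return List with `reads` (named character vector) and `truth` (list
#'   with per-read `reads` provenance data.frame, per-taxon `taxa`
#'   fractions and the expected per-gene read `shares`).
#' @export
simulate_reads <- function(spec, refs, n_reads, read_length = 100L,
                           error_rate = 0.01, seed = NULL,
                           rrna_amplification = NULL) {
  validate_taxon_spec(spec)
  if (!is.null(refs$databases)) refs <- refs$databases
  if (n_reads <= 0) stop("n_reads must be positive", call. = FALSE)
  if (error_rate >= 0.1) stop("error_rate must be < 0.1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  tab <- do.call(rbind, lapply(names(refs), function(gene) {
    rec <- refs[[gene]]$records
    taxon <- sub(paste0("_", gene, "$"), "", rec$record_id)
    idx <- match(taxon, spec$name)
    cp <- copies_for_gene(spec, gene)[idx]
    w <- spec$fraction[idx] * cp * rec$length_bp
    if (grepl("^rRNA", gene) && !is.null(rrna_amplification)) {
      amp <- rrna_amplification[taxon]
      amp[is.na(amp)] <- 1
      w <- w * amp
    }
    data.frame(gene = gene, taxon = taxon, reference_id = rec$record_id,
               sequence = rec$sequence, length_bp = rec$length_bp,
               weight = w, stringsAsFactors = FALSE)
  }))
  tab <- tab[tab$weight > 0, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no gene has positive sampling weight",
                            call. = FALSE)
  if (read_length > min(tab$length_bp))
    stop("read_length exceeds the shortest simulated gene", call. = FALSE)

  counts <- as.vector(rmultinom(1, n_reads, tab$weight / sum(tab$weight)))
  src <- rep(seq_len(nrow(tab)), counts)
  n <- length(src)
  starts <- vapply(seq_len(n), function(i)
    sample.int(tab$length_bp[src[i]] - read_length + 1L, 1L), integer(1))
  seqs <- substring(tab$sequence[src], starts, starts + read_length - 1L)

  n_err <- rbinom(n, read_length, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(read_length, n_err[i])
    v <- strsplit(seqs[i], "")[[1]]
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }
  flip <- runif(n) < 0.5
  seqs[flip] <- reverse_complement(seqs[flip])
  ids <- sprintf("read%07d", seq_len(n))
  reads <- setNames(seqs, ids)

  shares <- tab[, c("gene", "taxon", "reference_id", "weight")]
  shares$share_total <- shares$weight / sum(shares$weight)
  shares$share_within_gene <- stats::ave(shares$weight, shares$gene,
                                         FUN = function(w) w / sum(w))
  truth <- list(
    reads = data.frame(read_id = ids, taxon = tab$taxon[src],
                       gene = tab$gene[src],
                       reference_id = tab$reference_id[src],
                       start = starts - 1L,
                       strand = ifelse(flip, "-", "+"),
                       n_errors = n_err, stringsAsFactors = FALSE),
    taxa = spec[, c("name", "group", "fraction")],
    shares = shares)
  list(reads = reads, truth = truth)
}

#' Default per-group cell geometry for the optical simulator
#'
#' Major/minor axes in micrometres (typical cell sizes per group) and a
#' bead-standardized side-scatter value defined as `major^3`, so that the
#' power law `d = a * ssc^b` with `a = 1, b = 1/3` recovers the diameter.
#'
#' @return data.frame with `group`, `major`, `minor`, `ssc`.
#' @export
group_geometry <- function() {
  g <- data.frame(
    group = c("Prochlorococcus", "Synechococcus", "chlorophytes",
              "pelagophytes", "haptophytes", "diatoms", "dinoflagellates",
              "heterotrophic_bacteria", "other"),
    major = c(0.6, 1.0, 2.0, 2.5, 6.0, 20.0, 25.0, 0.5, 5.0),
    minor = c(0.6, 1.0, 1.8, 2.2, 5.0, 12.0, 20.0, 0.5, 4.0),
    stringsAsFactors = FALSE)
  g$ssc <- g$major^3
  g
}

#' Simulate an optical (microscopy / flow-cytometry) count table
#'
#' Cell counts are multinomial in the true fractions; per-taxon geometry is
#' the group mean perturbed by a lognormal factor with coefficient of
#' variation `noise_cv` (0 = exact group means).
#'
#' @param spec taxon specification.
#' @param n_cells total cells counted (>= 100).
#' @param noise_cv lognormal coefficient of variation on the axes.
#' @param seed RNG seed.
#' @param mode `"axes"` (confocal-style major/minor axes) or `"ssc"`
#'   (flow-cytometry-style side scatter).
#' @param geometry per-group geometry table (see [group_geometry()]).
#' @return data.frame with `sample_id`, `taxon`, `group`, `cell_count` and
#'   geometry columns.
#' @export
simulate_optical_counts <- function(spec, n_cells = 10000L, noise_cv = 0.2,
                                    seed = NULL, mode = c("axes", "ssc"),
                                    geometry = group_geometry()) {
  validate_taxon_spec(spec)
  mode <- match.arg(mode)
  if (n_cells < 100L) stop("n_cells must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- as.vector(rmultinom(1, n_cells, spec$fraction))
  gi <- match(spec$group, geometry$group)
  sdlog <- sqrt(log(1 + noise_cv^2))
  factor_ <- if (noise_cv > 0)
    exp(rnorm(nrow(spec), -sdlog^2 / 2, sdlog)) else rep(1, nrow(spec))
  out <- data.frame(sample_id = "sim", taxon = spec$name,
                    group = spec$group, cell_count = counts,
                    stringsAsFactors = FALSE)
  if (mode == "axes") {
    out$major_axis <- geometry$major[gi] * factor_
    out$minor_axis <- geometry$minor[gi] * factor_
  } else {
    out$ssc <- geometry$ssc[gi] * factor_^3
  }
  out
}
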