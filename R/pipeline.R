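# Command-line pipeline: subcommand dispatch, flag parsing, config echoes
# and exit codes (0 success, 2 usage error, 3 data error).  Flags mirror
# the recruitment parameter names used throughout the package
# (--min-read-size, --identity, --alignment, --complexity-percent,
# --complexity-number) with the same defaults (70/80/80/75/30; support 0.7).

usage_error <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

data_error <- function(...) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

# read a file through `fn`, turning any parse failure into a data error
parse_or_die <- function(path, fn, ...) {
  if (!file.exists(path)) data_error("input file not found: %s", path)
  tryCatch(fn(path, ...),
           error = function(e) data_error("failed to parse %s: %s", path,
                                          conditionMessage(e)))
}

# --flag value parser; `defs` maps flag name -> list(type, default)
# (default NA = required); returns a named list of converted values
parse_flags <- function(args, defs) {
  vals <- lapply(defs, `[[`, "default")
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) usage_error("unexpected argument '%s'", a)
    key <- substring(a, 3L)
    if (!key %in% names(defs)) usage_error("unknown flag --%s", key)
    if (i == length(args)) usage_error("flag --%s needs a value", key)
    raw <- args[[i + 1L]]
    vals[[key]] <- switch(defs[[key]]$type,
      integer = {
        v <- suppressWarnings(as.integer(raw))
        if (is.na(v)) usage_error("--%s expects an integer, got '%s'",
                                  key, raw)
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(raw))
        if (is.na(v)) usage_error("--%s expects a number, got '%s'",
                                  key, raw)
        v
      },
      character = raw)
    i <- i + 2L
  }
  need <- names(defs)[vapply(vals, function(v) identical(v, NA),
                             logical(1))]
  if (length(need) > 0L)
    usage_error("missing required flag --%s", need[[1]])
  vals
}

flag <- function(type, default = NA) list(type = type, default = default)

recruitment_flag_defs <- function() list(
  `min-read-size` = flag("integer", 70L),
  identity = flag("numeric", 80),
  alignment = flag("numeric", 80),
  `complexity-percent` = flag("numeric", 75),
  `complexity-number` = flag("integer", 30L))

params_from_flags <- function(fl) {
  tryCatch(
    recruitment_params(min_read_size = fl$`min-read-size`,
                       min_identity = fl$identity,
                       min_aligned_fraction = fl$alignment,
                       complexity_percent = fl$`complexity-percent`,
                       complexity_number = fl$`complexity-number`),
    error = function(e) usage_error("%s", conditionMessage(e)))
}

ensure_out_dir <- function(dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    data_error("cannot create output directory %s", dir)
  dir
}

# reproducibility record written by every subcommand; contains no
# timestamps so reruns on identical inputs are byte-identical
write_config_echo <- function(out_dir, subcommand, seed, params, inputs) {
  md5 <- if (length(inputs) > 0L)
    as.list(unname(tools::md5sum(inputs))) else list()
  names(md5) <- basename(inputs)
  cfg <- list(tool = "psbOquant",
              version = as.character(utils::packageVersion("psbOquant")),
              subcommand = subcommand, seed = seed, parameters = params,
              input_md5 = md5)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(cfg)
}

log_msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

load_databases <- function(paths) {
  dbs <- lapply(paths, parse_or_die, fn = parse_reference_fasta)
  names(dbs) <- vapply(dbs, `[[`, character(1), "gene")
  dbs
}

cli_simulate <- function(args, quiet) {
  fl <- parse_flags(args, list(
    seed = flag("integer"), `out-dir` = flag("character"),
    community = flag("character", "mock"),
    `phototroph-fraction` = flag("numeric", 0.15),
    `n-taxa` = flag("integer", 6L),
    `n-reads` = flag("integer", 100000L),
    `read-length` = flag("integer", 100L),
    `error-rate` = flag("numeric", 0.01),
    divergence = flag("numeric", 0.15),
    genes = flag("character", "psbO,recA,rRNA_16S,rRNA_18S")))
  out <- ensure_out_dir(fl$`out-dir`)
  spec <- switch(fl$community,
                 mock = mock_community(),
                 bacterio = bacterio_community(fl$`phototroph-fraction`),
                 random = random_community(fl$`n-taxa`, seed = fl$seed),
                 usage_error("unknown --community '%s'", fl$community))
  genes <- strsplit(fl$genes, ",", fixed = TRUE)[[1]]
  refs <- simulate_reference_set(spec, divergence = fl$divergence,
                                 seed = fl$seed, genes = genes)
  sim <- simulate_reads(spec, refs, n_reads = fl$`n-reads`,
                        read_length = fl$`read-length`,
                        error_rate = fl$`error-rate`,
                        seed = fl$seed + 1L)
  for (g in names(refs$databases))
    write_reference_fasta(refs$databases[[g]],
                          file.path(out, sprintf("refs_%s.fasta", g)))
  write_reads_fasta(sim$reads, file.path(out, "reads.fasta"))
  write_tsv(sim$truth$reads, file.path(out, "truth_reads.tsv"),
            comments = "# per-read provenance (simulated)")
  write_tsv(sim$truth$taxa, file.path(out, "truth_taxa.tsv"),
            comments = "# true cell fractions (simulated)")
  if (!is.null(refs$tree)) {
    ape::write.tree(refs$tree$tree, file.path(out, "psbO_tree.nwk"))
    aln <- refs$alignment$rows
    writeLines(paste0(">", names(aln), "\n", unname(aln)),
               file.path(out, "psbO_protein_alignment.fasta"))
  }
  write_config_echo(out, "simulate", fl$seed,
                    fl[setdiff(names(fl), c("out-dir"))], character(0))
  log_msg(quiet, "simulate: %d taxa, %d reads -> %s", nrow(spec),
          length(sim$reads), out)
  0L
}

cli_recruit <- function(args, quiet) {
  fl <- parse_flags(args, c(list(
    reads = flag("character"), db = flag("character"),
    `out-dir` = flag("character")), recruitment_flag_defs()))
  out <- ensure_out_dir(fl$`out-dir`)
  params <- params_from_flags(fl)
  db_paths <- strsplit(fl$db, ",", fixed = TRUE)[[1]]
  dbs <- load_databases(db_paths)
  reads <- parse_or_die(fl$reads, read_reads)
  res <- recruit(reads, dbs, params)
  write_recruitment_tsv(res, file.path(out, "hits.tsv"),
                        file.path(out, "rejected.tsv"))
  write_config_echo(out, "recruit", NULL, params,
                    c(fl$reads, db_paths))
  log_msg(quiet, "recruit: %d/%d reads recruited", nrow(res$hits),
          res$total_input_reads)
  0L
}

# rebuild the minimal recruitment result a profile run needs from hits.tsv
recruitment_from_tsv <- function(path) {
  hits <- parse_or_die(path, read_tsv)
  need <- c("read_id", "reference_id", "ref_start", "ref_end")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L)
    data_error("%s lacks required column '%s'", path, miss[1])
  structure(list(hits = hits, rejected = data.frame(),
                 total_input_reads = NA_integer_,
                 total_mapped_reads = nrow(hits),
                 params = recruitment_params()),
            class = "recruitment_result")
}

cli_profile <- function(args, quiet) {
  fl <- parse_flags(args, list(
    hits = flag("character"), db = flag("character"),
    `out-dir` = flag("character"),
    `sample-id` = flag("character", "sample1"),
    `size-fraction` = flag("character", "0.2-3"),
    `length-normalization` = flag("character", "covered")))
  out <- ensure_out_dir(fl$`out-dir`)
  db_paths <- strsplit(fl$db, ",", fixed = TRUE)[[1]]
  dbs <- load_databases(db_paths)
  res <- recruitment_from_tsv(fl$hits)
  stats <- coverage_stats(res, dbs)
  ab <- abundance_table(stats, sample_id = fl$`sample-id`,
                        size_fraction = fl$`size-fraction`,
                        length_normalization = fl$`length-normalization`)
  write_abundance_tsv(ab, file.path(out, "abundance.tsv"))
  psbo <- ab[ab$gene == "psbO", , drop = FALSE]
  attributes(psbo)[c("sample_id", "size_fraction", "total_mapped_reads",
                     "class")] <-
    attributes(ab)[c("sample_id", "size_fraction", "total_mapped_reads",
                     "class")]
  agg <- aggregate_by_taxon(psbo, by = "group")
  write_abundance_tsv(agg, file.path(out, "psbO_groups.tsv"))
  rel <- relative_abundance(agg, "total_phytoplankton")
  write_abundance_tsv(rel, file.path(out, "psbO_relative.tsv"))
  write_config_echo(out, "profile", NULL,
                    fl[c("sample-id", "size-fraction",
                         "length-normalization")],
                    c(fl$hits, db_paths))
  log_msg(quiet, "profile: %d references, %d psbO groups", nrow(ab),
          nrow(agg))
  0L
}

cli_ratio <- function(args, quiet) {
  fl <- parse_flags(args, list(
    abundance = flag("character"), `out-dir` = flag("character"),
    mode = flag("character", "bacteria")))
  out <- ensure_out_dir(fl$`out-dir`)
  ab <- parse_or_die(fl$abundance, read_tsv)
  for (col in c("gene", "group", "rpkm"))
    if (!col %in% names(ab))
      data_error("%s lacks required column '%s'", fl$abundance, col)
  ratios <- switch(fl$mode,
    bacteria = list(phototroph_fraction_bacteria(
      gene_rpkm(ab, "psbO", cyanobacteria_groups()),
      gene_rpkm(ab, "recA"))),
    eukaryotes = list(phototroph_fraction_eukaryotes(
      gene_rpkm(ab, "psbO",
                setdiff(unique(ab$group), cyanobacteria_groups())),
      vapply(sprintf("rp%02d", 1:25), function(g)
        if (g %in% ab$gene) gene_rpkm(ab, g) else NA_real_, numeric(1)))),
    rieske = list(rieske_ratio(gene_rpkm(ab, "petC_chloroplast"),
                               gene_rpkm(ab, "rieske_mitochondrial"))),
    usage_error("unknown --mode '%s' (bacteria, eukaryotes, rieske)",
                fl$mode))
  write_ratio_tsv(ratios, file.path(out, "ratios.tsv"))
  write_config_echo(out, "ratio", NULL, fl["mode"], fl$abundance)
  log_msg(quiet, "ratio [%s]: %s", fl$mode,
          format(ratios[[1]]$raw_ratio))
  0L
}

cli_classify <- function(args, quiet) {
  fl <- parse_flags(args, list(
    queries = flag("character"), alignment = flag("character"),
    tree = flag("character"), db = flag("character"),
    `out-dir` = flag("character"),
    `support-threshold` = flag("numeric", 0.7)))
  out <- ensure_out_dir(fl$`out-dir`)
  queries <- parse_or_die(fl$queries, read_reads)
  ref_aln <- parse_or_die(fl$alignment, read_reference_alignment)
  db <- parse_or_die(fl$db, parse_reference_fasta)
  phy <- parse_or_die(fl$tree, ape::read.tree)
  tip_groups <- setNames(
    db$records$group[match(phy$tip.label, db$records$record_id)],
    phy$tip.label)
  if (anyNA(tip_groups))
    data_error("tree tip '%s' has no record in %s",
               phy$tip.label[which(is.na(tip_groups))[1]], fl$db)
  tree <- reference_tree(phy, tip_groups)
  cls <- classify_fragments(queries, ref_aln, tree,
                            support_threshold = fl$`support-threshold`)
  write_tsv(cls, file.path(out, "classifications.tsv"),
            comments = c("# phylogenetic placement classifications",
                         sprintf("# support threshold: > %s (strict)",
                                 fl$`support-threshold`)))
  write_config_echo(out, "classify", NULL, fl["support-threshold"],
                    c(fl$queries, fl$alignment, fl$tree, fl$db))
  log_msg(quiet, "classify: %d fragments", nrow(cls))
  0L
}

cli_stats <- function(args, quiet) {
  fl <- parse_flags(args, list(
    abundance = flag("character"), `out-dir` = flag("character"),
    counts = flag("character", ""),
    `ssc-a` = flag("numeric", NA_real_), `ssc-b` = flag("numeric", NA_real_)))
  out <- ensure_out_dir(fl$`out-dir`)
  ab <- parse_or_die(fl$abundance, read_tsv)
  for (col in c("taxon", "rpkm"))
    if (!col %in% names(ab))
      data_error("%s lacks required column '%s'", fl$abundance, col)
  rows <- data.frame(statistic = "shannon_rpkm",
                     value = shannon(ab$rpkm), n = nrow(ab),
                     stringsAsFactors = FALSE)
  inputs <- fl$abundance
  if (nzchar(fl$counts)) {
    ct <- parse_or_die(fl$counts, read_tsv)
    coeffs <- if (!is.na(fl$`ssc-a`)) list(a = fl$`ssc-a`, b = fl$`ssc-b`)
    bio <- relative_biovolume(ct, ssc_coeffs = coeffs)
    write_tsv(bio, file.path(out, "biovolume.tsv"),
              comments = "# relative biovolume per taxon (percent sums to 100)")
    rows <- rbind(rows, data.frame(statistic = "shannon_cell_counts",
                                   value = shannon(tapply(ct$cell_count,
                                                          ct$taxon, sum)),
                                   n = length(unique(ct$taxon))))
    shared <- intersect(ab$taxon, unique(ct$taxon))
    if (length(shared) >= 4L) {
      cnt <- tapply(ct$cell_count, ct$taxon, sum)[shared]
      sp <- spearman_rho(ab$rpkm[match(shared, ab$taxon)],
                         as.numeric(cnt))
      rows <- rbind(rows,
        data.frame(statistic = c("spearman_rho_vs_counts",
                                 "spearman_p_vs_counts"),
                   value = c(sp$rho, sp$p_value), n = length(shared)))
    }
    inputs <- c(inputs, fl$counts)
  }
  write_tsv(rows, file.path(out, "stats.tsv"),
            comments = "# community statistics (Shannon uses natural log)")
  write_config_echo(out, "stats", NULL, fl[c("ssc-a", "ssc-b")], inputs)
  log_msg(quiet, "stats: %d statistics", nrow(rows))
  0L
}

cli_demo <- function(args, quiet) {
  fl <- parse_flags(args, c(list(
    seed = flag("integer"), `out-dir` = flag("character"),
    `n-reads` = flag("integer", 10000L)), recruitment_flag_defs()))
  out <- ensure_out_dir(fl$`out-dir`)
  params <- params_from_flags(fl)
  spec <- mock_community()
  log_msg(quiet, "demo: simulating references and %d reads (seed %d)",
          fl$`n-reads`, fl$seed)
  refs <- simulate_reference_set(spec, seed = fl$seed)
  sim <- simulate_reads(spec, refs, n_reads = fl$`n-reads`,
                        seed = fl$seed + 1L)
  for (g in names(refs$databases))
    write_reference_fasta(refs$databases[[g]],
                          file.path(out, sprintf("refs_%s.fasta", g)))
  write_reads_fasta(sim$reads, file.path(out, "reads.fasta"))
  write_tsv(sim$truth$taxa, file.path(out, "truth_taxa.tsv"),
            comments = "# true cell fractions (simulated)")
  log_msg(quiet, "demo: recruiting")
  res <- recruit(sim$reads, refs$databases, params)
  write_recruitment_tsv(res, file.path(out, "hits.tsv"),
                        file.path(out, "rejected.tsv"))
  ab <- abundance_table(coverage_stats(res, refs$databases))
  write_abundance_tsv(ab, file.path(out, "abundance.tsv"))
  psbo <- ab[ab$gene == "psbO", , drop = FALSE]
  attributes(psbo)[c("sample_id", "size_fraction", "total_mapped_reads",
                     "class")] <-
    attributes(ab)[c("sample_id", "size_fraction", "total_mapped_reads",
                     "class")]
  rel <- relative_abundance(aggregate_by_taxon(psbo), "total_phytoplankton")
  write_abundance_tsv(rel, file.path(out, "psbO_relative.tsv"))
  write_config_echo(out, "demo", fl$seed,
                    c(params, list(n_reads = fl$`n-reads`)), character(0))
  log_msg(quiet, "demo: %d/%d reads recruited; psbO percentages written",
          nrow(res$hits), res$total_input_reads)
  0L
}

pipeline_usage <- function() paste(
  "usage: psboquant <subcommand> [--flag value ...]",
  "",
  "subcommands:",
  "  simulate  simulate reference sets and reads for a mock community",
  "  recruit   recruit reads onto marker databases (Smith-Waterman)",
  "  profile   rpkm abundance profiles from recruitment hits",
  "  ratio     phototroph-fraction ratios (psbO/recA etc.)",
  "  classify  phylogenetic placement classification of fragments",
  "  stats     Shannon / Spearman / biovolume statistics",
  "  demo      simulate -> recruit -> profile -> report, fully seeded",
  "",
  "recruitment flags (defaults): --min-read-size 70, --identity 80,",
  "  --alignment 80, --complexity-percent 75, --complexity-number 30",
  sep = "\n")

#' Run the command-line pipeline
#'
#' Dispatches one of the subcommands `simulate`, `recruit`, `profile`,
#' `ratio`, `classify`, `stats` or `demo` and returns an exit status
#' (0 success, 2 usage error, 3 data error).  Every run writes a
#' `config.json` echo (tool version, seed, parameters, input checksums) so
#' results are reproducible; outputs contain no timestamps, so reruns on
#' unchanged inputs are byte-identical.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  quiet <- "--quiet" %in% args
  args <- args[args != "--quiet"]
  if (length(args) == 0L || args[[1]] %in% c("--help", "-h", "help")) {
    message(pipeline_usage())
    return(invisible(if (length(args) == 0L) 2L else 0L))
  }
  sub <- args[[1]]
  rest <- args[-1]
  handler <- switch(sub, simulate = cli_simulate, recruit = cli_recruit,
                    profile = cli_profile, ratio = cli_ratio,
                    classify = cli_classify, stats = cli_stats,
                    demo = cli_demo, NULL)
  status <- tryCatch({
    if (is.null(handler)) usage_error("unknown subcommand '%s'", sub)
    handler(rest, quiet)
  },
  usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    message(pipeline_usage())
    2L
  },
  data_error = function(e) {
    message("data error: ", conditionMessage(e))
    3L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}
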