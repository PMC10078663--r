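# Mock-community simulator: spec validation, reference evolution,
# read sampling model and optical counts.

test_that("community specs enforce the abundance-model invariants", {
  spec <- mock_community()
  expect_equal(sum(spec$fraction), 1)
  expect_true(all(spec$psbO_copies <= 2))
  bad <- spec; bad$fraction[1] <- bad$fraction[1] + 0.1
  expect_error(psbOquant:::validate_taxon_spec(bad), "sum to 1")
  bad2 <- spec; bad2$photosynthetic[1] <- FALSE
  expect_error(psbOquant:::validate_taxon_spec(bad2), "psbO")
  bad3 <- spec; bad3$psbO_copies[1] <- 3L
  expect_error(psbOquant:::validate_taxon_spec(bad3), "at most 2")
})

test_that("bacterio communities split the phototroph fraction 2:1", {
  spec <- bacterio_community(0.15)
  expect_equal(spec$fraction[spec$group == "Prochlorococcus"], 0.10)
  expect_equal(spec$fraction[spec$group == "Synechococcus"], 0.05)
  expect_equal(sum(spec$fraction[!spec$photosynthetic]), 0.85)
  expect_true(all(spec$psbO_copies[!spec$photosynthetic] == 0))
})

test_that("divergence 0 produces identical references", {
  spec <- mock_community()
  refs <- simulate_reference_set(spec, divergence = 0, seed = 5,
                                 genes = "psbO")
  expect_identical(length(unique(refs$databases$psbO$records$sequence)), 1L)
})

test_that("realized divergence is within 3 SD of the binomial expectation", {
  # two taxa, divergence 0.2, length 600 (spec'd check, seed 43)
  spec <- mock_community()[c(3, 5), ]
  spec$fraction <- c(0.5, 0.5)
  refs <- simulate_reference_set(spec, divergence = 0.2, seed = 43,
                                 genes = "psbO",
                                 gene_lengths = c(psbO = 600L))
  s <- refs$databases$psbO$records$sequence
  diffs <- mapply(function(a, b) sum(a != b),
                  strsplit(s[1], ""), strsplit(s[2], ""))
  # with one pair, mean pairwise divergence is the pair's divergence
  expect_lt(abs(diffs - 0.2 * 600), 3 * sqrt(600 * 0.2 * 0.8))
})

test_that("fixed seeds reproduce reference sets byte-identically", {
  spec <- mock_community()
  a <- simulate_reference_set(spec, seed = 9, genes = c("psbO", "recA"))
  b <- simulate_reference_set(spec, seed = 9, genes = c("psbO", "recA"))
  expect_identical(a$databases$psbO$records, b$databases$psbO$records)
  expect_identical(ape::write.tree(a$tree$tree), ape::write.tree(b$tree$tree))
  expect_identical(a$alignment$rows, b$alignment$rows)
})

test_that("groups are monophyletic on the simulated taxon tree", {
  spec <- bacterio_community(0.3) # 2 groups with 1 taxon, 1 with 4
  refs <- simulate_reference_set(spec, seed = 2, genes = "recA")
  phy <- refs$taxon_tree
  het <- spec$name[spec$group == "heterotrophic_bacteria"]
  mrca <- ape::getMRCA(phy, het)
  tips <- phy$tip.label[phangorn::Descendants(phy, mrca, "tips")[[1]]]
  expect_setequal(tips, het)
})

test_that("no two simulated references are nearly identical", {
  # separation floor: minimum pairwise divergence >= one third of the mean
  spec <- mock_community()
  for (s in 1:3) {
    refs <- simulate_reference_set(spec, divergence = 0.15, seed = s,
                                   genes = "psbO")
    seqs <- strsplit(refs$databases$psbO$records$sequence, "")
    n <- length(seqs)
    pd <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      pd <- c(pd, mean(seqs[[i]] != seqs[[j]]))
    expect_gte(min(pd), mean(pd) / 3 - 0.02)
  }
})

test_that("incompatible divergence x length errors out", {
  spec <- mock_community()
  expect_error(simulate_reference_set(spec, divergence = 0.001, seed = 1,
                                      genes = "psbO"),
               "expected differences")
  expect_error(simulate_reference_set(spec, divergence = 0.6, seed = 1),
               "divergence")
})

test_that("psbO databases only contain photosynthetic taxa", {
  spec <- bacterio_community(0.2)
  refs <- simulate_reference_set(spec, seed = 3,
                                 genes = c("psbO", "recA"))
  expect_setequal(refs$databases$psbO$records$group,
                  c("Prochlorococcus", "Synechococcus"))
  expect_identical(nrow(refs$databases$recA$records), nrow(spec))
})

test_that("equal single-copy taxa receive equal reads within 3 SD (seed 47)", {
  spec <- mock_community()[c(3, 4), ]
  spec$fraction <- c(0.5, 0.5)
  refs <- simulate_reference_set(spec, seed = 47, genes = "psbO")
  sim <- simulate_reads(spec, refs, n_reads = 1e4, seed = 47)
  counts <- table(sim$truth$reads$taxon)
  expect_lt(abs(counts[[1]] - 5000), 3 * sqrt(1e4 * 0.25))
})

test_that("error_rate 0 makes every read an exact (rev-complemented) substring", {
  spec <- mock_community()[c(3, 4), ]
  spec$fraction <- c(0.5, 0.5)
  refs <- simulate_reference_set(spec, seed = 13, genes = "psbO")
  sim <- simulate_reads(spec, refs, n_reads = 50, error_rate = 0,
                        seed = 14)
  recs <- refs$databases$psbO$records
  for (i in seq_along(sim$reads)) {
    src <- recs$sequence[recs$record_id ==
                           sim$truth$reads$reference_id[i]]
    r <- sim$reads[[i]]
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(r, "")[[1]]), collapse = ""))
    expect_true(grepl(r, src, fixed = TRUE) ||
                  grepl(rc, src, fixed = TRUE))
  }
  # and both strands occur
  expect_setequal(unique(sim$truth$reads$strand), c("+", "-"))
})

test_that("rRNA read counts scale with copy number (seed 53)", {
  spec <- mock_community()[c(3, 4), ] # two eukaryotes, equal abundance
  spec$fraction <- c(0.5, 0.5)
  spec$rRNA_copies <- c(100L, 1L)
  spec$petC_copies <- 0L; spec$rieske_copies <- 0L; spec$rp_copies <- 0L
  refs <- simulate_reference_set(spec, seed = 53,
                                 genes = c("psbO", "rRNA_18S"))
  sim <- simulate_reads(spec, refs, n_reads = 2e4, seed = 53)
  tr <- sim$truth$reads
  rr <- table(tr$taxon[tr$gene == "rRNA_18S"])
  ps <- table(tr$taxon[tr$gene == "psbO"])
  expect_gt(rr[[spec$name[1]]] / rr[[spec$name[2]]], 50)
  expect_lt(ps[[spec$name[1]]] / ps[[spec$name[2]]], 1.5)
  expect_gt(ps[[spec$name[1]]] / ps[[spec$name[2]]], 1 / 1.5)
})

test_that("truth tables record the sampling-model shares", {
  spec <- mock_community()
  refs <- simulate_reference_set(spec, seed = 21,
                                 genes = c("psbO", "rRNA_18S"))
  sim <- simulate_reads(spec, refs, n_reads = 1000, seed = 22)
  sh <- sim$truth$shares
  expect_equal(sum(sh$share_total), 1, tolerance = 1e-12)
  within <- tapply(sh$share_within_gene, sh$gene, sum)
  expect_true(all(abs(within - 1) < 1e-12))
  # psbO shares equal cell fractions for single-copy equal-length genes
  ps <- sh[sh$gene == "psbO", ]
  expect_equal(ps$share_within_gene[order(ps$taxon)],
               spec$fraction[order(spec$name)])
})

test_that("read length longer than the shortest gene is an error", {
  spec <- mock_community()
  refs <- simulate_reference_set(spec, seed = 1, genes = "psbO")
  expect_error(simulate_reads(spec, refs, n_reads = 10, read_length = 500L,
                              seed = 1), "read_length")
  expect_error(simulate_reads(spec, refs, n_reads = 0, seed = 1),
               "n_reads")
  expect_error(simulate_reads(spec, refs, n_reads = 10, error_rate = 0.2,
                              seed = 1), "error_rate")
})

test_that("optical counts recover fractions within 3 SD at zero noise", {
  spec <- mock_community()
  oc <- simulate_optical_counts(spec, n_cells = 1e4, noise_cv = 0,
                                seed = 59)
  expect_identical(sum(oc$cell_count), 10000L)
  g <- group_geometry()
  expect_equal(oc$major_axis,
               g$major[match(oc$group, g$group)]) # exact group means
  p <- oc$cell_count / sum(oc$cell_count)
  sd3 <- 3 * sqrt(spec$fraction * (1 - spec$fraction) / 1e4)
  expect_true(all(abs(p - spec$fraction) <= sd3))
})

test_that("optical simulation is seed-deterministic", {
  spec <- mock_community()
  a <- simulate_optical_counts(spec, seed = 3)
  b <- simulate_optical_counts(spec, seed = 3)
  expect_identical(a, b)
})
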