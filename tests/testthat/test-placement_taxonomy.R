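# Placement taxonomy: six-frame translation, profile alignment,
# minimum-distance placement and the monophyly + support rule.

test_that("six-frame translation matches a hand-written codon table", {
  set.seed(31)
  for (k in 1:5) {
    nt <- random_dna(91)
    for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      expect_identical(psbOquant:::translate_frame(nt, f),
                       oracle_translate(nt, f))
    }
  }
})

test_that("internal stop codons are kept as * and scored, not fatal", {
  nt <- paste0("ATG", "TAA", "ATGGCTGCTAAA")
  expect_identical(psbOquant:::translate_frame(nt, 1L), "M*MAAK")
})

# a small protein profile: three gapless rows plus one row with a gap
toy_alignment <- function() {
  reference_alignment(c(
    r1 = "MSTALKVQEDGRWFNPYHICMSTALKVQEDGRWFNPYHIC",
    r2 = "MSTALKVQEDGKWFNPYHICMSTALKVQEDGRWFNPYHIC",
    r3 = "MSTELKVQEDGRWFNPYH-CMSTALKVEEDGRWFNPYHIC"))
}

test_that("best frame is recovered for a coding fragment in any frame", {
  aln <- toy_alignment()
  aa <- substr(aln$rows[["r1"]], 1, 30)
  # back-translate with a fixed codon choice, then shift/flip the fragment
  codon_of <- c(M = "ATG", S = "TCT", T = "ACT", A = "GCT", L = "CTT",
                K = "AAA", V = "GTT", Q = "CAA", E = "GAA", D = "GAT",
                G = "GGT", R = "CGT", W = "TGG", F = "TTT", N = "AAT",
                P = "CCT", Y = "TAT", H = "CAT", I = "ATT", C = "TGT")
  nt <- paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")
  got1 <- best_frame_translate(nt, aln)
  expect_identical(got1$frame, 1L)
  expect_identical(got1$aa, aa)
  got2 <- best_frame_translate(paste0("GG", nt), aln)
  expect_identical(got2$frame, 3L)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
  gotrc <- best_frame_translate(rc, aln)
  expect_identical(gotrc$frame, -1L)
  expect_identical(gotrc$aa, aa)
})

test_that("random nucleotide junk is reported untranslatable or low-scoring", {
  aln <- toy_alignment()
  res <- best_frame_translate(strrep("GCGC", 20), aln)
  # either no frame scores above 0, or the winning score is small
  if (is.na(res$frame)) {
    expect_identical(res$reason, "untranslatable")
  } else {
    expect_lt(res$score, 30)
  }
})

test_that("profile alignment maps an exact fragment onto its own columns", {
  aln <- toy_alignment()
  frag <- substr(aln$rows[["r2"]], 6, 30)
  al <- align_to_profile(frag, aln)
  expect_identical(al$columns, 6:30)
  expect_identical(substr(al$aligned, 6, 30), frag)
  expect_false(al$low_confidence)
  # reference columns are never altered: width preserved
  expect_identical(nchar(al$aligned), aln$width)
})

test_that("profile alignment refuses fragments it cannot accommodate", {
  aln <- toy_alignment()
  expect_error(align_to_profile("MSTALK", aln), "20")
  expect_error(align_to_profile(strrep("MSTALKVQED", 9), aln), "twice")
})

test_that("placement distance is the Poisson-corrected mismatch fraction", {
  aln <- toy_alignment()
  tree <- reference_tree(
    ape::read.tree(text = "((r1:1,r2:1)0.9:1,r3:2)0.8;"),
    c(r1 = "diatoms", r2 = "diatoms", r3 = "haptophytes"))
  # query equal to r2 on 40 columns except 2 residues -> p = 0.05
  q <- aln$rows[["r2"]]
  substr(q, 1, 1) <- "W"; substr(q, 3, 3) <- "W"
  pl <- place_query(q, aln, tree, "q1")
  expect_identical(pl$nearest_reference_id, "r2")
  expect_equal(pl$distance, -log(1 - 2 / 40))
  expect_identical(pl$shared_columns, 40L)
})

test_that("placement ties break toward the smallest reference id", {
  aln <- reference_alignment(c(zeta = strrep("MSTALKVQED", 3),
                               alpha = strrep("MSTALKVQED", 3)))
  tree <- reference_tree(
    ape::read.tree(text = "(zeta:1,alpha:1)0.9;"),
    c(zeta = "diatoms", alpha = "diatoms"))
  pl <- place_query(strrep("MSTALKVQED", 3), aln, tree)
  expect_identical(pl$nearest_reference_id, "alpha")
})

test_that("queries sharing fewer than 20 columns are unplaceable", {
  aln <- toy_alignment()
  tree <- reference_tree(
    ape::read.tree(text = "((r1:1,r2:1)0.9:1,r3:2)0.8;"),
    c(r1 = "diatoms", r2 = "diatoms", r3 = "haptophytes"))
  q <- paste0(substr(aln$rows[["r1"]], 1, 10), strrep("-", 30))
  pl <- place_query(q, aln, tree, "q")
  expect_true(pl$unplaceable)
})

test_that("classification agrees with exhaustive clade enumeration", {
  rt <- fixture_tree12()
  phy <- rt$tree
  ntip <- length(phy$tip.label)
  for (node in seq_len(ntip + phy$Nnode)) {
    got <- classify_placement(rt, if (node <= ntip)
      phy$tip.label[node] else node)
    want <- oracle_classify(phy, rt$tip_groups, rt$supports, node, 0.7)
    expect_identical(got, want,
                     info = sprintf("attachment node %d", node))
  }
})

test_that("support exactly at the threshold never classifies", {
  rt <- fixture_tree12()
  # t05/t06 sit under a pure chlorophyte node with support exactly 0.7;
  # everything above is mixed, so the strict rule must say unclassified
  expect_identical(classify_placement(rt, "t05"), "unclassified")
  expect_identical(classify_placement(rt, "t06"), "unclassified")
  # lowering the threshold below 0.7 classifies the same attachment
  expect_identical(classify_placement(rt, "t05", support_threshold = 0.69),
                   "chlorophytes")
})

test_that("nodes without support values are skipped, not treated as 1", {
  rt <- fixture_tree12()
  # t11/t12's parent has no label (NA support) and higher nodes are mixed
  expect_identical(classify_placement(rt, "t11"), "unclassified")
})

test_that("unrooted trees are midpoint-rooted with a message", {
  nwk <- "(t1:1,t2:1,t3:4);"
  expect_message(
    rt <- reference_tree(ape::read.tree(text = nwk),
                         c(t1 = "diatoms", t2 = "diatoms",
                           t3 = "haptophytes")),
    "midpoint")
  expect_true(ape::is.rooted(rt$tree))
})
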