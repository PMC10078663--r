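# Read recruitment: parameter bounds, complexity screen, Smith-Waterman
# alignment against independent oracles, filter semantics and best-hit
# tie-breaking.

permissive <- recruitment_params(min_read_size = 10L, min_identity = 1e-6,
                                 min_aligned_fraction = 1e-6,
                                 complexity_percent = 100,
                                 complexity_number = 1L)

test_that("parameter percentages outside (0, 100] are rejected", {
  expect_error(recruitment_params(min_identity = 101), "identity")
  expect_error(recruitment_params(min_identity = 0), "identity")
  expect_error(recruitment_params(min_aligned_fraction = 120), "fraction")
  expect_error(recruitment_params(min_read_size = 0), "read")
})

test_that("align_read agrees exactly with the Smith-Waterman DP oracle", {
  set.seed(421)
  ref <- random_dna(300)
  for (k in 1:25) {
    read <- if (k %% 2 == 0) random_dna(80) else {
      # high-identity read: mutated substring, sometimes reversed
      s <- sample(200, 1)
      r <- substring(ref, s, s + 79)
      v <- strsplit(r, "")[[1]]
      pos <- sample(80, 3)
      v[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
      r <- paste(v, collapse = "")
      if (k %% 4 == 1)
        chartr("ACGT", "TGCA", paste(rev(strsplit(r, "")[[1]]),
                                     collapse = "")) else r
    }
    got <- align_read(read, ref, permissive)
    want <- oracle_align_read(read, ref, permissive)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$score, want$score)
      expect_equal(got$matches, want$matches)
      expect_equal(got$columns, want$columns)
      expect_equal(got$ref_start, want$ref_start)
      expect_equal(got$ref_end, want$ref_end)
      expect_equal(got$read_start, want$read_start)
      expect_equal(got$read_end, want$read_end)
      expect_identical(got$strand, want$strand)
    }
  }
})

test_that("alignment scores match Biostrings local alignment", {
  set.seed(97)
  submat <- psbOquant:::nucleotide_submat()
  for (k in 1:20) {
    read <- random_dna(70); ref <- random_dna(200)
    hit <- align_read(read, ref, permissive)
    bs <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref),
      type = "local", substitutionMatrix = submat,
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
    rcr <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    bs_rc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rcr), Biostrings::DNAString(ref),
      type = "local", substitutionMatrix = submat,
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
    expect_identical(hit$score, as.integer(max(bs, bs_rc)))
  }
})

test_that("a 69-nt perfect read is rejected and a 70-nt one recruited", {
  db <- tiny_db()
  ref <- db$records$sequence[1]
  r69 <- substring(ref, 1, 69)
  r70 <- substring(ref, 1, 70)
  res <- recruit(c(a = r69, b = r70), db)
  expect_identical(res$rejected$read_id, "a")
  expect_identical(res$rejected$reason, "too_short")
  expect_identical(res$hits$read_id, "b")
  expect_identical(res$hits$identity, 100)
})

test_that("identity 79.9% is rejected and exactly 80.0% is recruited", {
  # 1000-nt reads against a 1200-nt reference; mismatches are interior and
  # separated by runs of matches, so the full-length ungapped alignment is
  # the Smith-Waterman optimum and identity is exactly (1000 - k)/1000
  ref <- fixture_long_dna()
  db <- reference_db(data.frame(
    record_id = "long", gene = "psbO", group = "Prochlorococcus",
    taxonomy = "Bacteria;Cyanobacteria;Prochlorococcus",
    sequence = ref, stringsAsFactors = FALSE))
  base <- substring(ref, 101, 1100)
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  r799 <- mutate_at(base, unique(round(seq(5, 995, length.out = 201))))
  r800 <- mutate_at(base, unique(round(seq(5, 995, length.out = 200))))
  res <- recruit(c(at799 = r799, at800 = r800), db)
  expect_identical(res$rejected$read_id, "at799")
  expect_identical(res$rejected$reason, "low_identity")
  expect_identical(res$hits$read_id, "at800")
  expect_equal(res$hits$identity, 80)
  expect_equal(res$hits$aligned_read_fraction, 100)
})

test_that("rejection reasons follow the filter order", {
  db <- tiny_db()
  ref <- db$records$sequence[1]
  reads <- c(short = substring(ref, 1, 50),
             homopolymer = strrep("A", 100),
             unrelated = substring(fixture_seq_c(), 1, 100),
             good = substring(ref, 1, 100))
  res <- recruit(reads, db)
  rej <- setNames(res$rejected$reason, res$rejected$read_id)
  expect_identical(unname(rej["short"]), "too_short")
  expect_identical(unname(rej["homopolymer"]), "low_complexity")
  expect_true(rej["unrelated"] %in% c("no_hit", "low_identity",
                                      "low_coverage"))
  expect_identical(res$hits$read_id, "good")
})

test_that("complexity screen matches its definition at the boundaries", {
  p <- recruitment_params()
  # a homopolymer has 1 distinct 3-mer (< 30) and 100% dominant k-mer
  expect_false(complexity_pass(strrep("A", 100), p)$pass)
  # random 100-mers essentially always pass
  set.seed(7)
  expect_true(complexity_pass(random_dna(100), p)$pass)
  # reads shorter than k + complexity_number windows cannot pass
  expect_false(complexity_pass(strrep("ACGT", 5), p)$pass)
})

test_that("best-hit ties break toward the smallest reference id", {
  shared <- substring(fixture_seq_c(), 1, 100)
  seq1 <- paste0(shared, substring(fixture_seq_d(), 1, 100))
  seq2 <- paste0(shared, substring(fixture_seq_d(), 101, 200))
  db <- reference_db(data.frame(
    record_id = c("zeta", "alpha"), gene = "psbO", group = "diatoms",
    taxonomy = "Eukaryota;diatoms", sequence = c(seq1, seq2),
    stringsAsFactors = FALSE))
  res <- recruit(c(r = shared), db) # identical prefix of both references
  expect_identical(res$hits$reference_id, "alpha")
})

test_that("reads are recruited on the strand they came from", {
  db <- tiny_db()
  ref <- db$records$sequence[1]
  fwd <- substring(ref, 1, 100)
  res <- recruit(c(f = fwd, r = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))), db)
  expect_identical(res$hits$strand[res$hits$read_id == "f"], "+")
  expect_identical(res$hits$strand[res$hits$read_id == "r"], "-")
})

test_that("recruitment counts are conserved", {
  set.seed(11)
  db <- tiny_db()
  reads <- c(substring(db$records$sequence[1], 1, 100),
             substring(db$records$sequence[2], 21, 120),
             random_dna(100), strrep("AT", 50), "ACGT")
  names(reads) <- paste0("r", 1:5)
  res <- recruit(reads, db)
  expect_identical(nrow(res$hits) + nrow(res$rejected), 5L)
  expect_identical(res$total_input_reads, 5L)
  expect_identical(res$total_mapped_reads, nrow(res$hits))
})

test_that("ribotag classifier applies length, N and LCA rules", {
  ribo <- reference_db(data.frame(
    record_id = c("d1", "d2", "h1"), gene = "rRNA_18S",
    group = c("diatoms", "diatoms", "haptophytes"),
    taxonomy = c("Eukaryota;diatoms;Thalassiosira",
                 "Eukaryota;diatoms;Chaetoceros",
                 "Eukaryota;haptophytes;Emiliania"),
    sequence = c(strrep("ACGTTGCAAGGTCCATGCAA", 10),
                 strrep("ACGTTGCAAGGTCCATGCAA", 10),
                 strrep("TTGACCGGTAAACCTGGATC", 10)),
    stringsAsFactors = FALSE))
  frag <- substring(ribo$records$sequence[1], 1, 120)
  hit <- classify_ribotag(frag, ribo)
  # two identical references tie -> LCA truncates to the shared prefix
  expect_identical(hit$taxonomy, c("Eukaryota", "diatoms"))
  expect_identical(hit$n_tied_hits, 2L)
  expect_identical(classify_ribotag(substring(frag, 1, 99), ribo)$reason,
                   "too_short")
  expect_identical(
    classify_ribotag(paste0(substring(frag, 1, 119), "N"), ribo)$reason,
    "contains_N")
  expect_identical(classify_ribotag(strrep("ACCTG", 24), ribo)$reason,
                   "no_hit")
})
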