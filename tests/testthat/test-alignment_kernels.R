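# Alignment engine kernels: scalar / SSE2 / AVX2 score agreement, best-end
# tie semantics, the k-mer prescreen + windowed traceback inside recruit(),
# and the small C++ utility kernels.

striped_engines <- function() setdiff(psbOquant:::.sw_engines_cpp(), "scalar")

rdna_n <- function(n) paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                                   prob = c(.24, .24, .24, .24, .04)),
                            collapse = "")

test_that("all available engines agree with the scalar DP on score and end", {
  set.seed(511)
  params <- list(c(1L, -2L, -1L, -1L), c(1L, -1L, -2L, -1L),
                 c(2L, -3L, -5L, -2L))
  for (p in params) {
    for (k in 1:25) {
      q <- rdna_n(sample(8:250, 1))
      r <- rdna_n(sample(15:1500, 1))
      want <- psbOquant:::.sw_score_cpp(q, r, p[1], p[2], p[3], p[4], "scalar")
      for (e in striped_engines()) {
        got <- psbOquant:::.sw_score_cpp(q, r, p[1], p[2], p[3], p[4], e)
        expect_identical(got$score, want$score,
                         info = sprintf("%s score, params %s", e,
                                        paste(p, collapse = ",")))
        expect_identical(got$ref_end, want$ref_end,
                         info = sprintf("%s ref_end", e))
      }
    }
  }
})

test_that("scores above the 8-bit range fall back to wider lanes exactly", {
  q <- strrep("ACGT", 200) # perfect 800-bp read; score 800 with +1 match
  r <- paste0("TTTT", q, "GGGG")
  want <- psbOquant:::.sw_score_cpp(q, r, 1L, -2L, -1L, -1L, "scalar")
  expect_identical(want$score, 800L)
  for (e in striped_engines()) {
    got <- psbOquant:::.sw_score_cpp(q, r, 1L, -2L, -1L, -1L, e)
    expect_identical(got$score, 800L)
    expect_identical(got$ref_end, want$ref_end)
  }
})

test_that("the reported best end is the smallest column attaining the max", {
  # two identical optimal regions; everything must point at the first
  set.seed(902)
  motif <- random_dna(80)
  ref <- paste0(random_dna(150), motif, random_dna(200), motif,
                random_dna(100))
  read <- motif
  substr(read, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, 40, 40))[1]
  want <- psbOquant:::.sw_score_cpp(read, ref, 1L, -1L, -2L, -1L, "scalar")
  expect_identical(want$ref_end, 230L) # end of the first copy
  for (e in striped_engines()) {
    got <- psbOquant:::.sw_score_cpp(read, ref, 1L, -1L, -2L, -1L, e)
    expect_identical(got$ref_end, want$ref_end)
  }
})

# exhaustive best-hit oracle over a reference table, mirroring the
# documented recruit() semantics (score, identity, columns, smallest
# reference id, forward strand)
oracle_recruit_best <- function(read, rec, params) {
  best <- NULL
  strands <- list(`+` = toupper(read),
                  `-` = psbOquant:::reverse_complement(toupper(read)))
  for (j in seq_len(nrow(rec))) {
    for (s in c("+", "-")) {
      a <- psbOquant:::.sw_align_cpp(strands[[s]], toupper(rec$sequence[j]),
                                     params$match, params$mismatch,
                                     params$gap_open, params$gap_extend)
      if (!a$found) next
      a$j <- j; a$s <- s
      take <- is.null(best)
      if (!take && a$score > best$score) take <- TRUE
      if (!take && a$score == best$score) {
        li <- a$matches * best$columns
        lb <- best$matches * a$columns
        if (li > lb) take <- TRUE
        else if (li == lb) {
          if (a$columns > best$columns) take <- TRUE
          else if (a$columns == best$columns && a$j < best$j) take <- TRUE
        }
      }
      if (take) best <- a
    }
  }
  best
}

test_that("recruit() equals exhaustive enumeration on a divergent database", {
  spec <- mock_community()
  refs <- simulate_reference_set(spec, divergence = 0.2, seed = 71,
                                 genes = "psbO")
  db <- refs$databases$psbO
  rec <- db$records[order(db$records$record_id), , drop = FALSE]
  params <- recruitment_params(min_identity = 50, min_aligned_fraction = 50,
                               complexity_number = 5)
  set.seed(72)
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    s
  }
  reads <- character(0)
  for (k in c(0L, 3L, 10L)) {
    for (i in 1:12) {
      src <- rec$sequence[sample(nrow(rec), 1)]
      st <- sample(nchar(src) - 100, 1)
      frag <- substr(src, st, st + 99)
      if (runif(1) < 0.5) frag <- psbOquant:::reverse_complement(frag)
      reads <- c(reads, mutate(frag, k))
    }
  }
  reads <- c(reads, replicate(8, random_dna(100))) # unrelated junk
  names(reads) <- sprintf("q%02d", seq_along(reads))

  res <- recruit(reads, db, params)
  seen <- c(res$hits$read_id, res$rejected$read_id)
  expect_setequal(seen, names(reads))
  for (id in names(reads)) {
    want <- oracle_recruit_best(reads[[id]], rec, params)
    hit <- res$hits[res$hits$read_id == id, ]
    if (is.null(want)) {
      expect_identical(res$rejected$reason[res$rejected$read_id == id],
                       "no_hit")
      next
    }
    identity <- 100 * want$matches / want$columns
    frac <- 100 * (want$read_end - want$read_start) / nchar(reads[[id]])
    if (identity < params$min_identity ||
        frac < params$min_aligned_fraction) {
      expect_identical(nrow(hit), 0L, info = id)
      expect_true(res$rejected$reason[res$rejected$read_id == id] %in%
                    c("low_identity", "low_coverage"), info = id)
      next
    }
    expect_identical(nrow(hit), 1L, info = id)
    expect_identical(hit$reference_id, rec$record_id[want$j], info = id)
    expect_identical(hit$score, want$score, info = id)
    expect_identical(hit$matches, want$matches, info = id)
    expect_identical(hit$columns, want$columns, info = id)
    expect_identical(hit$ref_start, want$ref_start, info = id)
    expect_identical(hit$ref_end, want$ref_end, info = id)
    expect_identical(hit$strand, want$s, info = id)
    expect_equal(hit$identity, identity, info = id)
  }
})

test_that("recruit() best hits are exact on repeat-laden references", {
  # tandem repeats maximize alignment-end ties and stress the windowed
  # traceback's smallest-end guarantee
  set.seed(73)
  unit <- random_dna(37)
  rec <- data.frame(
    record_id = c("rep_a", "rep_b"),
    gene = "psbO", group = "diatoms", taxonomy = "Eukaryota;diatoms",
    sequence = c(strrep(unit, 12), paste0(random_dna(50), strrep(unit, 8))),
    stringsAsFactors = FALSE)
  rec$length_bp <- nchar(rec$sequence)
  db <- structure(list(gene = "psbO", records = rec), class = "reference_db")
  params <- recruitment_params(min_identity = 50, min_aligned_fraction = 50,
                               complexity_number = 5)
  reads <- setNames(
    c(substr(strrep(unit, 4), 10, 109),
      psbOquant:::reverse_complement(substr(strrep(unit, 4), 3, 102)),
      substr(paste0(strrep(unit, 2), random_dna(40)), 1, 100)),
    c("r1", "r2", "r3"))
  res <- recruit(reads, db, params)
  rec_sorted <- rec[order(rec$record_id), , drop = FALSE]
  for (id in names(reads)) {
    want <- oracle_recruit_best(reads[[id]], rec_sorted, params)
    hit <- res$hits[res$hits$read_id == id, ]
    expect_identical(hit$reference_id, rec_sorted$record_id[want$j], info = id)
    expect_identical(hit$score, want$score, info = id)
    expect_identical(hit$ref_start, want$ref_start, info = id)
    expect_identical(hit$ref_end, want$ref_end, info = id)
    expect_identical(hit$strand, want$s, info = id)
  }
})

test_that("kmer statistics match a direct R count", {
  set.seed(81)
  for (i in 1:10) {
    s <- rdna_n(sample(5:120, 1))
    for (k in c(1L, 3L)) {
      got <- psbOquant:::.kmer_stats_cpp(s, k)
      subs <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
      subs <- subs[!grepl("N", subs, fixed = TRUE)]
      if (length(subs) == 0) {
        expect_identical(got, c(0L, 0L, 0L))
      } else {
        tab <- table(subs)
        expect_identical(got[1], length(tab))
        expect_identical(got[2], as.integer(max(tab)))
        expect_identical(got[3], length(subs))
      }
    }
  }
})

test_that("fit alignment differences match a direct R dynamic program", {
  oracle_fit <- function(read, ref) {
    q <- strsplit(read, "")[[1]]; r <- strsplit(ref, "")[[1]]
    m <- length(q); n <- length(r)
    prev <- rep(0L, n + 1) # free leading reference gap
    for (i in 1:m) {
      cur <- integer(n + 1); cur[1] <- i
      for (j in 1:n) {
        d <- prev[j] + as.integer(!(q[i] == r[j] && q[i] != "N"))
        cur[j + 1] <- min(d, prev[j + 1] + 1L, cur[j] + 1L)
      }
      prev <- cur
    }
    min(prev)
  }
  set.seed(83)
  for (i in 1:8) {
    read <- rdna_n(sample(10:40, 1))
    ref <- rdna_n(sample(30:200, 1))
    expect_identical(psbOquant:::.fit_diffs_cpp(read, ref),
                     oracle_fit(read, ref))
  }
})

test_that("profile alignment columns are strictly increasing", {
  set.seed(85)
  for (i in 1:5) {
    m <- sample(5:15, 1); W <- m + sample(0:20, 1)
    cs <- matrix(rnorm(m * W), m, W)
    al <- psbOquant:::.profile_align_cpp(cs, -3, -1)
    expect_identical(length(al$columns), m)
    expect_true(all(diff(al$columns) >= 1))
    expect_true(all(al$columns >= 1 & al$columns <= W))
  }
})
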