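# Independent reference implementations ("oracles") used to check the
# package's primitives.  These are written directly from the mathematical
# definitions, in plain R, and deliberately share no code with the package.

# --- full Smith-Waterman DP oracle -----------------------------------------
# Affine gaps: a gap of length L costs gap_open + (L-1)*gap_extend.
# Best cell: highest score, ties -> smallest reference end, then smallest
# read end.  Traceback preference: diagonal, then gap-consuming-reference,
# then gap-consuming-read; leaving a gap run via its opening step is
# preferred over extending.
oracle_sw <- function(read, ref, match = 1, mismatch = -1,
                      gap_open = -2, gap_extend = -1) {
  q <- strsplit(toupper(read), "")[[1]]
  r <- strsplit(toupper(ref), "")[[1]]
  m <- length(q); n <- length(r)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  subsc <- function(a, b) {
    if (a %in% c("A", "C", "G", "T") && a == b) match else mismatch
  }
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    e <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
    f <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
    d <- H[i, j] + subsc(q[i], r[j])
    h <- max(0, d, e, f)
    E[i + 1, j + 1] <- e; F[i + 1, j + 1] <- f; H[i + 1, j + 1] <- h
    if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
      best <- h; bi <- i; bj <- j
    }
  }
  if (best <= 0)
    return(list(found = FALSE, score = 0))
  i <- bi; j <- bj; state <- "H"
  matches <- 0; columns <- 0
  repeat {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      d <- H[i, j] + subsc(q[i], r[j])
      if (h == d) {
        columns <- columns + 1
        if (q[i] == r[j] && q[i] %in% c("A", "C", "G", "T"))
          matches <- matches + 1
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E" else state <- "F"
    } else if (state == "E") {
      columns <- columns + 1
      e <- E[i + 1, j + 1]
      if (e == H[i + 1, j] + gap_open) state <- "H"
      j <- j - 1
    } else {
      columns <- columns + 1
      f <- F[i + 1, j + 1]
      if (f == H[i, j + 1] + gap_open) state <- "H"
      i <- i - 1
    }
  }
  list(found = TRUE, score = best, matches = matches, columns = columns,
       read_start = i, read_end = bi, ref_start = j, ref_end = bj)
}

# both-strand oracle mirroring align_read's contract (forward preferred on
# score ties); returns NULL below the identity / aligned-fraction cutoffs
oracle_align_read <- function(read, ref, params) {
  fw <- oracle_sw(read, ref, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(read),
                                                    "")[[1]]),
                                       collapse = ""))
  rv <- oracle_sw(rc, ref, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  hit <- NULL; strand <- NULL
  if (fw$found && (!rv$found || fw$score >= rv$score)) {
    hit <- fw; strand <- "+"
  } else if (rv$found) {
    hit <- rv; strand <- "-"
  }
  if (is.null(hit)) return(NULL)
  identity <- 100 * hit$matches / hit$columns
  frac <- 100 * (hit$read_end - hit$read_start) / nchar(read)
  if (identity < params$min_identity || frac < params$min_aligned_fraction)
    return(NULL)
  c(hit, list(identity = identity, aligned_read_fraction = frac,
              strand = strand))
}

# --- translation oracle -----------------------------------------------------
oracle_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
}

oracle_translate <- function(nt, frame) {
  tab <- oracle_codon_table()
  s <- toupper(nt)
  if (frame < 0)
    s <- chartr("ACGTN", "TGCAN",
                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  off <- abs(frame) - 1
  s <- substring(s, off + 1)
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- tab[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# --- Spearman enumeration oracle --------------------------------------------
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- oracle_perms(n - 1L)
  out <- list()
  for (p in smaller) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

oracle_spearman <- function(x, y) {
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  n <- length(x)
  ry <- rank(y)
  rhos <- vapply(oracle_perms(n), function(p)
    suppressWarnings(cor(rank(x), ry[p])), numeric(1))
  list(rho = rho, p_value = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# --- placement classification enumeration oracle ----------------------------
# Walks rootward from the attachment node; the fragment is classified at the
# first node whose support is recorded, strictly exceeds the threshold, and
# whose tip set carries a single group label.
oracle_classify <- function(phy, tip_groups, supports, node, threshold) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  path <- node
  while (path[length(path)] != root) {
    e <- which(phy$edge[, 2] == path[length(path)])
    path <- c(path, phy$edge[e, 1])
  }
  for (nd in path) {
    if (nd <= ntip) next
    sup <- supports[nd - ntip]
    if (is.na(sup) || sup <= threshold) next
    tips <- phangorn::Descendants(phy, nd, "tips")[[1]]
    gr <- unique(tip_groups[phy$tip.label[tips]])
    if (length(gr) == 1L) return(unname(gr))
  }
  "unclassified"
}

# --- small shared fixtures ---------------------------------------------------
# fixed random sequences (literals so tests never depend on RNG state)
fixture_seq_a <- function() paste0(
  "CACTCTAGTACCGGGTTGCCTCTAAAACCTGCGATCACGACCTAGGAGTTTGTCCTGTGCACAGACTCTC",
  "CGGCCATCACCATGACTGTACTATAACGACTAAATAGGTGCGCTGATGCAACTGTTTGAGCAAGAGCACT",
  "CTTGCTGACGCACACAAATGCGAGCGTTCCAGAGGAACAGGCGGCACGTCTTCCACGGAG")

fixture_seq_b <- function() paste0(
  "TGTCACGGGTGAGGCAGGTCGAAATAAACAGGAGAGAGTAATAAGAAGCACGTTCCAAGTTCTTAAATTC",
  "ACTCGTCCGGAGTATATTATCCCCTCCTACGTCTTCTTCACCGATTGATATCCTAGCAGATCTTGACAAA",
  "TATTTGACAGGCAGCTAGTCCACGAGGTATCCCTAGAATTAGGGACACACTCGTCCACCA")

fixture_seq_c <- function() paste0(
  "AGGCGCAGAAGGATATACTACATACGAATGAAATCTGTGAGCTCGCCCGGAACAATTGTGATTGTGCCCG",
  "CCTGCGGGTTCTAACAAGAAAATCGGGAATATGACCGCAGGGCTAGAATATGCTCTTCTGATCCCGTGTG",
  "TTCGGTCTAGTAATGCATAAGCCAGGTGGAAACACTTGAAAAACAACATTAAAGCATTGA")

fixture_seq_d <- function() paste0(
  "CAGAAATAACTCAACATTCATATACCCCGTTGACCTCACCTACAGAATCATTTACCTTGCGAGGTGTCAA",
  "CACGGTAGGCTTTAGCGTGAAGCGTGAACAGAGTTGGAGCGATTTAAGGAGACCCGGAGTAGCGTCCTCA",
  "AAATGCCTCCTGGCCAACGCGACCCGTGAGAATATAAGGGTCCCCCCTACTGTTTGTAAT")

fixture_long_dna <- function() paste0(
  "CATCGCTTCCGTTTTCGTGCTTGCTAATACTGAACGTCGTGTTTTGCGGAACGGTCACCAAGTCCGTGTA",
  "TGACCTAATGGAACAGCCGAATTTCCCCCTCCTATTTCTTGGACACACACCGACTCCGTTTCTGGGAAAT",
  "CACAACTTATGTTCCAGAAGCTACCCGGGTGTGGTATCCTTGCTACTTTGGCAACCAGAATAAATGTTCG",
  "GTGATCAATAAAGGCCGTGAGCTAGAAGGGTCCCATGTACTCGGGGCTTACGCGCAAACGCCATAGCTCC",
  "CGTCCCTGTACTATGAAACCCAGCTTACCTGAGCGGCCAACTTTAACTTAGAACCTGGTTTCGCTCTGAA",
  "CGGGTACCATCGTGATTCGAAGCTGCGAGTCGCGACCTGTATTGCATTACAGTGTCATCGCACTAGTTCT",
  "GGATGACGACTCGATCCCAGTGGATGGTGGACGGTGTCCCTGTTAGTTCGGCGATCGTTGTCCCCAATTA",
  "CAACAACCTCCCTTGTAGTACTCGTCAGTGAAACTGGGTTGTAAATACTGGGTATCGTGTGATCTCGTAT",
  "GGTGAGGGTATCGTGGAGGGTTCCGAGATTCAGGCAGCGTAGGGCTTGCATCCAACGGAGTGTAACGCAC",
  "GCGTCACGGTCCTTACTAAGCTCGAGCGTGCTTTCTATAACCTAGGGGAGGCTTGATGAATCCACGAGAC",
  "GTTCAACCACTGTGTACCGGGGAGGCCGCCTGCCACTGAGTTACGCCCCTTGACACCCACCCCACATCGT",
  "ATATCTGACTCAAAGCTGCGTCTGTATTTTGCAGCCGTTTTCGTCCCCTGCGGGGTTCGGAACAGACCGT",
  "ATCCAAGCACGATCGTACAGAGCTACCATGGAAGTTCCCTTATACGCGTACAGGCCGGATTTTACGACGT",
  "AATTGGGTGAGGTGTACACTATCCTTAGGAAACAATATTCAGTCCTGTGATACTGATGCCATTGGCAAAT",
  "TTTTGTTGGCAGACCGGCCCAACACCGTCCATGTCAGGACATTCCGGTCAGACCTGGCCGAATCCTACTC",
  "TGGCGTACGGTACTCGGAAACCGTGCTCTATCCGCCAGAGATCCTACCGTTGGACCTATTTGAGGATGAT",
  "TCAAATAACGCAGTCTAACGGGTCACACGCGGCCCGTGAGCGAATGCGCGTCGCCGTGCTATAGTATGCA",
  "GCAGTACTAG")

tiny_db <- function() {
  reference_db(data.frame(
    record_id = c("proA", "synA"),
    gene = "psbO",
    group = c("Prochlorococcus", "Synechococcus"),
    taxonomy = c("Bacteria;Cyanobacteria;Prochlorococcus",
                 "Bacteria;Cyanobacteria;Synechococcus"),
    sequence = c(fixture_seq_a(), fixture_seq_b()),
    stringsAsFactors = FALSE), gene = "psbO", provenance = "test")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-built 12-leaf support-annotated tree with mixed supports: one node
# at exactly 0.7, one at NA (no label), pure and mixed-group clades
fixture_tree12 <- function() {
  nwk <- paste0(
    "(((t01:1,t02:1)0.9:1,(t03:1,t04:1)0.6:1)0.95:1,",
    "((t05:1,t06:1)0.7:1,((t07:1,t08:1)0.8:1,",
    "((t09:1,t10:1)1.0:1,(t11:1,t12:1):1)0.65:1)0.85:1)0.4:1)0.99;")
  groups <- setNames(
    c(rep("diatoms", 4), rep("chlorophytes", 2), rep("haptophytes", 2),
      rep("dinoflagellates", 4)),
    sprintf("t%02d", 1:12))
  reference_tree(ape::read.tree(text = nwk), groups)
}
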