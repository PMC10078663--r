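# Shannon diversity, Spearman with exact small-sample p, genetic distances
# and biovolume closed forms.

test_that("Shannon of a uniform community is ln(S)", {
  for (S in c(2, 5, 17, 100)) {
    expect_equal(shannon(rep(3.7, S)), log(S), tolerance = 1e-12)
  }
  # a single-taxon community has zero diversity
  expect_equal(shannon(c(5, 0, 0)), 0)
})

test_that("Shannon matches vegan on random abundance vectors", {
  skip_if_not_installed("vegan")
  set.seed(71)
  for (k in 1:10) {
    a <- rgamma(12, 1)
    expect_equal(shannon(a), unname(vegan::diversity(a, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("Shannon is scale-invariant and rejects bad input", {
  a <- c(4, 1, 9, 2)
  expect_equal(shannon(a), shannon(a / sum(a)))
  expect_error(shannon(c(1, -1)), "nonnegative")
  expect_error(shannon(c(0, 0)), "zero")
})

test_that("Spearman rho matches cor.test and p matches enumeration (ties)", {
  cases <- list(
    list(x = c(1, 2, 3, 4, 5, 6), y = c(2, 1, 4, 3, 6, 5)),
    list(x = c(1, 1, 2, 3, 4, 5), y = c(5, 3, 4, 2, 2, 1)),  # ties
    list(x = c(3, 1, 4, 1, 5, 9, 2), y = c(2, 7, 1, 8, 2, 8, 1)))
  for (cs in cases) {
    got <- spearman_rho(cs$x, cs$y)
    expect_equal(got$rho,
                 unname(suppressWarnings(
                   cor.test(cs$x, cs$y, method = "spearman")$estimate)))
    want <- oracle_spearman(cs$x, cs$y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$p_value, want$p_value)
    expect_identical(got$method, "exact_permutation")
  }
})

test_that("large samples switch to the t approximation", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_rho(x, y)
  expect_identical(got$method, "t_approximation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ct$estimate))
})

test_that("constant vectors make the correlation undefined", {
  got <- spearman_rho(rep(1, 5), 1:5)
  expect_true(got$undefined)
  expect_true(is.na(got$rho))
})

test_that("K2P distances match the closed form on two sequences", {
  # 200 sites, 20 transitions (A<->G), 10 transversions (A<->C)
  a <- strrep("A", 200)
  b <- paste0(strrep("G", 20), strrep("C", 10), strrep("A", 170))
  P <- 20 / 200; Q <- 10 / 200
  want <- 0.5 * log(1 / ((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
  d <- suppressWarnings(
    genetic_distances(c(s1 = a, s2 = b, s3 = chartr("A", "T", a)),
                      species = c("sp1", "sp1", "sp2"), model = "K2P"))
  expect_equal(unname(d$distances["s1", "s2"]), want, tolerance = 1e-12)
  # p-distance is the plain mismatch fraction
  dp <- suppressWarnings(
    genetic_distances(c(s1 = a, s2 = b, s3 = chartr("A", "T", a)),
                      species = c("sp1", "sp1", "sp2"),
                      model = "p_distance"))
  expect_equal(unname(dp$distances["s1", "s2"]), 0.15, tolerance = 1e-12)
})

test_that("gap/N columns are deleted pairwise and thin pairs are an error", {
  a <- paste0(strrep("A", 60), strrep("-", 140))
  b <- strrep("A", 200)
  c2 <- strrep("T", 200)
  d <- suppressWarnings(
    genetic_distances(c(x = a, y = b, z = c2),
                      species = c("s1", "s1", "s2"),
                      model = "p_distance"))
  expect_equal(unname(d$distances["x", "y"]), 0)
  short <- paste0(strrep("A", 30), strrep("-", 170))
  expect_error(genetic_distances(c(x = short, y = b, z = c2),
                                 species = c("s1", "s1", "s2")),
               "fewer than 50")
})

test_that("the barcoding-gap report partitions pairs correctly", {
  seqs <- c(a1 = strrep("A", 100),
            a2 = paste0(strrep("C", 2), strrep("A", 98)),   # 0.02 to a1
            b1 = paste0(strrep("T", 30), strrep("A", 70)),  # 0.30ish to a*
            b2 = paste0(strrep("T", 30), strrep("C", 2), strrep("A", 68)))
  d <- genetic_distances(seqs, species = c("A", "A", "B", "B"),
                         model = "p_distance")
  expect_identical(length(d$intraspecific), 2L)
  expect_identical(length(d$interspecific), 4L)
  expect_true(d$global_gap$gap)
  expect_true(all(d$per_species$local_gap))
})

test_that("singleton species are excluded from the intraspecific set", {
  seqs <- c(a1 = strrep("A", 100), a2 = paste0("CC", strrep("A", 98)),
            b1 = paste0(strrep("T", 30), strrep("A", 70)))
  expect_warning(
    d <- genetic_distances(seqs, species = c("A", "A", "B"),
                           model = "p_distance"),
    "single sequence")
  expect_identical(length(d$intraspecific), 1L)
})

test_that("equal axes reduce the ellipsoid to the sphere", {
  for (dm in c(0.6, 2, 20)) {
    expect_equal(ellipsoid_biovolume(dm, dm), (pi / 6) * dm^3,
                 tolerance = 1e-12)
  }
  expect_error(ellipsoid_biovolume(1, 2), "major")
})

test_that("side-scatter biovolume follows the calibrated power law", {
  co <- list(a = 2, b = 1 / 3)
  # d = 2 * ssc^(1/3); ssc = 27 -> d = 6 -> V = 36 pi
  expect_equal(sphere_biovolume_from_ssc(27, co), (pi / 6) * 216)
  expect_error(sphere_biovolume_from_ssc(27, list(a = 2)), "b")
  expect_error(sphere_biovolume_from_ssc(-1, co), "positive")
})

test_that("relative biovolume sums to 100 and refuses mixed geometry", {
  counts <- data.frame(taxon = c("dia", "din"), cell_count = c(10, 5),
                       major_axis = c(20, 25), minor_axis = c(12, 20))
  rb <- relative_biovolume(counts)
  expect_equal(sum(rb$percent), 100, tolerance = 1e-9)
  # biovolume weighting: fewer large cells can dominate numerous small ones
  counts2 <- data.frame(taxon = c("pro", "din"), cell_count = c(1000, 5),
                        major_axis = c(0.6, 25), minor_axis = c(0.6, 20))
  rb2 <- relative_biovolume(counts2)
  expect_gt(rb2$percent[rb2$taxon == "din"], 95)
  mixed <- data.frame(taxon = c("a", "b"), cell_count = c(1, 1),
                      major_axis = c(2, NA), minor_axis = c(2, NA),
                      ssc = c(NA, 8))
  expect_error(relative_biovolume(mixed, ssc_coeffs = list(a = 1, b = 1/3)),
               "allow_mixed")
  rb3 <- relative_biovolume(mixed, ssc_coeffs = list(a = 1, b = 1/3),
                            allow_mixed = TRUE)
  expect_equal(sum(rb3$percent), 100, tolerance = 1e-9)
})
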