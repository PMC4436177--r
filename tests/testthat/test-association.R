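test_that("association filter keeps >=5 markers and >=10 kb inclusively", {
  seg <- cnv_segments("S1", "chr1",
                      c(0, 0, 0, 0), c(50000, 10000, 9999, 50000),
                      1L, c(4L, 5L, 5L, 5L))
  kept <- filter_for_association(seg)
  expect_equal(kept$end, c(10000, 50000))
  expect_equal(nrow(filter_for_association(seg[0, ])), 0)
  seg$n_markers[1] <- NA
  expect_error(filter_for_association(seg), "without n_markers")
  expect_equal(nrow(filter_for_association(seg, min_markers = 0)), 3)
})

test_that("pseudo-markers are breakpoints with closed-containment carriers", {
  gm <- toy_genome()
  samples <- sample_sheet(c("A", "B"), "female", c("case", "control"))
  seg <- cnv_segments(c("A", "B"), "chr1", c(100, 150), c(200, 250),
                      1L, 10L)
  pm <- build_pseudomarkers(seg, samples, gm)
  expect_equal(pm$position, c(100, 150, 200, 250))
  expect_equal(vapply(pm$carriers, length, integer(1)), c(1L, 2L, 2L, 1L))
  expect_equal(pm$direction, rep("loss", 4))

  # one segment yields two markers carried by its own sample
  one <- build_pseudomarkers(seg[1, ], samples, gm)
  expect_equal(nrow(one), 2)
  expect_equal(one$carriers, list("A", "A"))

  # losses and gains never share a marker; bound of 2 per segment holds
  seg2 <- cnv_segments(c("A", "B"), "chr1", 100, 200, c(1L, 3L), 10L)
  pm2 <- build_pseudomarkers(seg2, samples, gm)
  expect_equal(nrow(pm2), 4)
  expect_equal(sort(unique(pm2$direction)), c("gain", "loss"))
})

test_that("exhaustive permutation p equals the enumeration tail", {
  labs <- stats::setNames(rep(c("case", "control"), each = 2),
                          c("a", "b", "c", "d"))
  pt <- permutation_test(c("a", "b"), labs, mode = "exhaustive")
  expect_equal(pt$empirical_p, 1 / 6)  # C(4,2) = 6, only one as extreme
  expect_equal(pt$observed, 2)
  # universal carriage ties every permutation
  pt_all <- permutation_test(names(labs), labs, mode = "exhaustive")
  expect_equal(pt_all$empirical_p, 1)
  big <- stats::setNames(rep(c("case", "control"), each = 40),
                         sprintf("S%d", 1:80))
  expect_error(permutation_test("S1", big, mode = "exhaustive"),
               "monte_carlo")
})

test_that("monte-carlo p uses the +1 correction and is seed-deterministic", {
  ids <- sprintf("S%d", 1:20)
  labs <- stats::setNames(rep(c("case", "control"), each = 10), ids)
  pt1 <- permutation_test(ids[1:6], labs, n_perm = 500, seed = 7)
  pt2 <- permutation_test(ids[1:6], labs, n_perm = 500, seed = 7)
  expect_identical(pt1, pt2)
  expect_gte(pt1$empirical_p, 1 / 501)
  # all-carrier marker: every permutation ties, p = 1
  expect_equal(permutation_test(ids, labs, n_perm = 100,
                                seed = 1)$empirical_p, 1)
})

test_that("monte-carlo agrees with exhaustive enumeration on tiny cohorts", {
  set.seed(13)
  ids <- sprintf("S%d", 1:8)
  labs <- stats::setNames(rep(c("case", "control"), each = 4), ids)
  for (k in c(1, 3, 5)) {
    carriers <- sample(ids, k)
    ex <- permutation_test(carriers, labs, mode = "exhaustive")
    mc <- permutation_test(carriers, labs, n_perm = 20000, seed = 17 + k)
    expect_lt(abs(mc$empirical_p - ex$empirical_p), 0.01)
  }
})

test_that("carrier odds ratios reproduce published-style values", {
  expect_equal(round_half_away(carrier_odds_ratio(43, 70, 103, 605), 2),
               7.76)
  expect_equal(round_half_away(carrier_odds_ratio(37, 70, 119, 605), 2),
               4.58)
  expect_equal(round_half_away(carrier_odds_ratio(6, 70, 1, 605), 2),
               56.63)
  flagged <- carrier_odds_ratio(5, 70, 0, 605)
  expect_true(is.na(flagged))
})

test_that("a planted locus is recovered as one merged significant locus", {
  gm <- toy_genome()
  set.seed(23)
  n_case <- 30; n_control <- 90
  ids <- sprintf("S%03d", seq_len(n_case + n_control))
  samples <- sample_sheet(ids, "female",
                          rep(c("case", "control"), c(n_case, n_control)))
  carrier <- c(stats::runif(n_case) < 0.6, stats::runif(n_control) < 0.02)
  seg <- cnv_segments(ids[carrier], "chr1", 50000, 80000, 3L, 15L)
  res <- associate(seg, samples, n_perm = 2000, seed = 7, threshold = 0.001,
                   genome = gm)
  expect_equal(nrow(res$loci), 1)
  expect_equal(res$loci$start, 50000)
  expect_equal(res$loci$end, 80000)
  expect_equal(res$loci$direction, "gain")
  expect_equal(res$loci$case_carriers, sum(carrier[1:n_case]))
  # nothing beats a carrier pattern this extreme: p sits at the MC floor
  expect_equal(res$loci$empirical_p, 1 / 2001)
  # determinism: same seed, same everything
  res2 <- associate(seg, samples, n_perm = 2000, seed = 7,
                    threshold = 0.001, genome = gm)
  expect_identical(res$loci, res2$loci)
  expect_identical(res$markers, res2$markers)
})

test_that("no carriers means no loci; distinct carrier sets do not merge", {
  gm <- toy_genome()
  samples <- sample_sheet(sprintf("S%d", 1:10), "female",
                          rep(c("case", "control"), each = 5))
  empty <- associate(cnv_segments(), samples, n_perm = 100, seed = 1,
                     genome = gm)
  expect_equal(nrow(empty$loci), 0)

  # two overlapping case-only segments in different samples: adjacent
  # significant markers with different carrier sets must stay two loci
  seg <- cnv_segments(c("S1", "S2"), "chr1", c(10000, 10000),
                      c(40000, 50000), 1L, 10L)
  res <- associate(seg, samples, n_perm = 200, seed = 3, threshold = 1,
                   genome = gm)
  expect_gt(nrow(res$loci), 1)
})

test_that("X markers are analysed per sex when stratified", {
  gm <- toy_genome()
  samples <- sample_sheet(sprintf("S%d", 1:8),
                          rep(c("male", "female"), each = 4),
                          rep(c("case", "control"), 4))
  seg <- cnv_segments(c("S1", "S5"), "chrX", 100000, 150000,
                      c(2L, 3L), 10L)  # male gain, female gain
  res <- associate(seg, samples, n_perm = 100, seed = 5, threshold = 1,
                   genome = gm)
  expect_setequal(unique(res$markers$analysis), c("x_male", "x_female"))
  expect_true(all(res$markers$n_cases == 2))
})

test_that("p-value formatting matches association-table conventions", {
  expect_equal(format_pvalue(c(1 / 100001, 5e-5, 6.7e-4, 0.94)),
               c("1.0E-5", "5.0E-5", "6.7E-4", "0.94"))
  expect_equal(round_half_away(c(56.625, -2.345, 2.344), 2),
               c(56.63, -2.35, 2.34))
})
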