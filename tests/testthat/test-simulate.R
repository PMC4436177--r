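small_cfg <- function(...) {
  sim_config(seed = 5, n_case_male = 10, n_case_female = 5,
             n_control_male = 20, n_control_female = 10,
             count_mean = 8, x_count_mean = 1, ...)
}

test_that("simulation is byte-identical under a fixed config", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a, b)
  # and sensitive to the seed
  c <- simulate_cohort(sim_config(seed = 6, n_case_male = 10,
                                  n_case_female = 5, n_control_male = 20,
                                  n_control_female = 10, count_mean = 8))
  expect_false(identical(a$segments, c$segments))
})

test_that("emitted segments respect genome bounds and marker assignment", {
  sim <- simulate_cohort(small_cfg())
  gm <- default_genome()
  lens <- gm$chromosomes$length[match(sim$segments$chrom,
                                      gm$chromosomes$chrom)]
  expect_true(all(sim$segments$start >= 0))
  expect_true(all(sim$segments$end <= lens))
  expect_true(all(sim$segments$length >= 1))
  expect_equal(sim$segments$n_markers,
               pmax(1L, as.integer(round(sim$segments$length / 2000))))
  # male X segments avoid the PARs so hemizygous logic always applies
  male <- sim$samples$sample_id[sim$samples$sex == "male"]
  mx <- sim$segments[sim$segments$chrom == "chrX" &
                       sim$segments$sample_id %in% male, ]
  par <- gm$par_intervals
  hits_par <- rep(FALSE, nrow(mx))
  for (i in seq_len(nrow(par))) {
    hits_par <- hits_par | (mx$chrom == par$chrom[i] &
                              mx$start < par$end[i] &
                              mx$end > par$start[i])
  }
  expect_false(any(hits_par))
})

test_that("per-sample counts track the configured mean at scale", {
  cfg <- sim_config(seed = 9, n_case_male = 51, n_case_female = 19,
                    n_control_male = 441, n_control_female = 164,
                    count_mean = 10, x_count_mean = 0)
  sim <- simulate_cohort(cfg)
  mean_count <- nrow(sim$segments) / nrow(sim$samples)
  expect_lt(abs(mean_count - 10) / 10, 0.1)
})

test_that("planted loci carry the configured membership and truth", {
  planted <- data.frame(chrom = "chr2", start = 5e6, end = 5.03e6,
                        direction = "loss", f_case = 0.5, f_control = 0.02,
                        n_markers = 20)
  cfg <- small_cfg(planted_loci = planted)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$planted[[1]]
  hit <- sim$segments$chrom == "chr2" & sim$segments$start == 5e6
  expect_setequal(sim$segments$sample_id[hit], truth$carriers)
  expect_true(all(sim$segments$copy_number[hit] == 1L))
  expect_true(all(sim$segments$n_markers[hit] == 20L))

  none <- small_cfg(planted_loci = transform(planted, f_case = 0,
                                             f_control = 0))
  expect_equal(length(simulate_cohort(none)$truth$planted[[1]]$carriers),
               0)
  expect_error(
    small_cfg(planted_loci = transform(planted, end = 9e9)),
    "outside genome bounds")
  expect_error(small_cfg(planted_loci = transform(planted, f_case = 2)),
               "frequencies")
})

test_that("count outliers are marked in truth and caught by QC", {
  cfg <- sim_config(seed = 21, n_case_male = 0, n_case_female = 0,
                    n_control_male = 30, n_control_female = 30,
                    count_mean = 10, count_dispersion = 50,
                    x_count_mean = 0,
                    outlier_fraction = 0.05, outlier_multiplier = 6)
  sim <- simulate_cohort(cfg)
  expect_equal(length(sim$truth$outliers), 3)
  qc <- apply_qc(sim$segments, sim$samples)
  expect_true(all(sim$truth$outliers %in%
                    qc$reports$control$excluded))
})

test_that("null male-X simulations produce near-unit size-class odds", {
  # theta = 1: the large-vs-small odds ratio between male cases and male
  # controls should hover around 1
  ors <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 100 + i, n_case_male = 60, n_case_female = 0,
                      n_control_male = 60, n_control_female = 0,
                      count_mean = 0, x_count_mean = 25,
                      x_large_enrichment_or = 1)
    sim <- simulate_cohort(cfg)
    tab <- build_burden_table(sim$segments, sim$samples, "x_male")
    sample_odds_ratio(tab, "haldane")
  }, numeric(1))
  expect_lt(abs(median(ors) - 1), 0.35)
})

test_that("jitter-free planted family gains are exactly recoverable", {
  cfg <- sim_config(
    seed = 3, count_mean = 5,
    families = list(list(family_id = "F1", n_affected = 2,
                         n_unaffected = 2),
                    list(family_id = "F2", n_affected = 2,
                         n_unaffected = 1),
                    list(family_id = "F3", n_affected = 2,
                         n_unaffected = 2)),
    planted_family_locus = list(chrom = "chr21", start = 45812755,
                                end = 45812755 + 14638,
                                direction = "gain", jitter = 0))
  fam <- simulate_families(cfg)
  expect_equal(sum(fam$samples$status == "affected"), 6)
  expect_true(all(fam$truth$realized$start == 45812755))

  # jittered breakpoints keep the shared core inside the planted interval
  cfg2 <- cfg
  cfg2$planted_family_locus$jitter <- 2000
  fam2 <- simulate_families(cfg2)
  core <- fam2$truth$realized
  expect_true(max(core$start) <= 45812755 + 2000)
  expect_true(min(core$end) >= 45812755 + 14638 - 2000)

  bad <- cfg
  bad$planted_family_locus$jitter <- 8000
  expect_error(simulate_families(bad), "jitter exceeds half")
})
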