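test_that("canonical TSV coordinates are 1-based inclusive on disk", {
  # a published-style row: start 110,224,384 with length 18,569
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tcopy_number\tn_markers",
               "S1\tchr1\t110224384\t110242952\t1\t12"), path)
  seg <- read_segments(path)
  expect_equal(seg$start, 110224383)
  expect_equal(seg$end, 110242952)
  expect_equal(seg$length, 18569)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_segments(seg, out)
  reread <- utils::read.table(out, header = TRUE, sep = "\t")
  expect_equal(reread$start, 110224384)  # shifted back to 1-based
})

test_that("header-only and empty files read as empty segment tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tchrom\tstart\tend\tcopy_number\tn_markers", path)
  expect_equal(nrow(read_segments(path)), 0)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_segments(read_segments(path), out)
  expect_equal(length(readLines(out)), 1)  # header only
})

test_that("segment round-trips are the identity in both dialects", {
  set.seed(42)
  n <- 100
  start <- sample.int(1e6, n)
  seg <- cnv_segments(sample(sprintf("S%d", 1:10), n, replace = TRUE),
                      sample(c("chr1", "chrX"), n, replace = TRUE),
                      start, start + sample.int(2e5, n),
                      sample(0:4, n, replace = TRUE),
                      sample.int(50, n, replace = TRUE))
  for (dialect in c("canonical_tsv", "bed")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_segments(seg, path, dialect)
    back <- read_segments(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(seg),
                 ignore_attr = TRUE)
  }
})

test_that("malformed rows and invalid coordinates are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tcopy_number\tn_markers",
               "S1\tchr1\tnot_a_number\t200\t1\t5"), path)
  expect_error(read_segments(path), "malformed start at data line 1")
  expect_error(cnv_segments("S1", "chr1", 200, 100, 1L),
               "end must exceed start")
  expect_error(cnv_segments("S1", "chr1", 100, 200, -1L),
               "non-negative")
})

test_that("sample sheets enforce family-id and uniqueness invariants", {
  expect_error(sample_sheet(c("A", "A"), "male", "case"), "duplicated")
  expect_error(sample_sheet("A", "male", "affected"),
               "family_id required")
  expect_error(sample_sheet("A", "male", "case", family_id = "F1"),
               "only allowed")
  sheet <- sample_sheet(c("A", "B"), c("male", "female"),
                        c("affected", "unaffected"), "F1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samples(sheet, path)
  expect_equal(as.data.frame(read_samples(path)), as.data.frame(sheet),
               ignore_attr = TRUE)
})

test_that("segment classification follows sex-specific expected ploidy", {
  gm <- toy_genome()
  cases <- data.frame(
    chrom = c("chr1", "chr1", "chrX", "chrX", "chrX", "chrX", "chrX"),
    cn =   c(2L,      3L,     1L,     2L,     2L,     1L,     2L),
    sex =  c("female","male", "male",  "male", "female","female","male"),
    start = c(100, 100, 100, 100, 100, 100, 10),
    end = c(200, 200, 200, 200, 200, 200, 200),
    expect = c("not_cnv", "autosomal_cnv", "not_cnv", "x_male_cnv",
               "not_cnv", "x_female_cnv", "par_excluded"))
  seg <- cnv_segments("S1", cases$chrom, cases$start, cases$end, cases$cn)
  expect_equal(classify_segments(seg, cases$sex, gm), cases$expect)
})

test_that("classification is total and errors only on unknown-sex X", {
  gm <- toy_genome()
  grid <- expand.grid(cn = 0:4, chrom = c("chr1", "chrX"),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  seg <- cnv_segments("S1", grid$chrom, 100, 200, grid$cn)
  cls <- classify_segments(seg, grid$sex, gm)
  expect_true(all(cls %in% c("not_cnv", "autosomal_cnv", "x_male_cnv",
                             "x_female_cnv", "par_excluded")))
  expect_equal(length(cls), nrow(grid))
  xseg <- cnv_segments("S1", "chrX", 100, 200, 1L)
  expect_error(classify_segments(xseg, "unknown", gm), "sex must be known")
  expect_error(
    classify_segments(cnv_segments("S1", "chr9", 1, 2, 1L), "male", gm),
    "not in genome model")
})

test_that("direction uses ploidy 1 on the male non-PAR X", {
  gm <- toy_genome()
  seg <- cnv_segments("S1", c("chr1", "chrX", "chrX", "chr1"),
                      100, 200, c(3L, 0L, 2L, 2L))
  expect_equal(direction_of(seg, c("male", "male", "male", "male"), gm),
               c("gain", "loss", "gain", "none"))
})

test_that("size bins use strict boundaries and partition all segments", {
  cfg <- size_bin_config()
  seg <- cnv_segments("S1", "chr1", 0,
                      c(10000, 10001, 100000, 100001, 549942),
                      1L)
  expect_equal(size_bin(seg, cfg),
               c("sub_threshold", "small", "small", "large", "large"))
  # small + large exhaust everything above min_size
  set.seed(7)
  lens <- sample.int(3e5, 500)
  seg <- cnv_segments("S1", "chr1", 0, lens, 1L)
  bins <- size_bin(seg, cfg)
  expect_equal(sum(bins %in% c("small", "large")),
               sum(lens > cfg$min_size))
  expect_error(size_bin_config(min_size = 2e5, large_threshold = 1e5),
               "min_size < large_threshold")
})

test_that("genome model round-trips through YAML and validates PARs", {
  gm <- toy_genome()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_genome(gm, path)
  back <- read_genome(path)
  expect_equal(back$chromosomes, gm$chromosomes)
  expect_equal(back$par_intervals, gm$par_intervals)
  expect_error(
    genome_model(data.frame(chrom = "chrX", length = 100),
                 data.frame(chrom = "chrX", start = 50, end = 200)),
    "within their chromosome bounds")
})
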