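#' Size-bin configuration
#'
#' Burden analysis stratifies segments by length into `small`
#' (`min_size < length <= large_threshold`) and `large`
#' (`length > large_threshold`); segments with `length <= min_size` are
#' `sub_threshold` and dropped from burden tables. Both boundaries are
#' strict "greater than" cuts, so a segment of exactly 10 kb is below
#' threshold and one of exactly 100 kb is small.
#'
#' @param min_size minimum length in bp for a segment to enter burden
#'   analysis (default 10,000).
#' @param large_threshold length in bp above which a segment counts as
#'   large (default 100,000).
#' @return a list of class `size_bin_config`.
#' @export
size_bin_config <- function(min_size = 10000, large_threshold = 100000) {
  if (!(min_size > 0 && min_size < large_threshold)) {
    stop("need 0 < min_size < large_threshold")
  }
  structure(list(min_size = min_size, large_threshold = large_threshold),
            class = "size_bin_config")
}

#' Classify segments relative to expected ploidy
#'
#' A called segment is a CNV only when its copy number departs from the
#' expected ploidy of its location in a sample of the given sex: 2 on
#' autosomes and on the female X, 1 on the male X outside the
#' pseudo-autosomal regions (PARs). Male X segments intersecting a PAR by
#' at least 1 bp are assigned `par_excluded` and take no part in any
#' analysis (the PAR is diploid in males, so hemizygous logic does not
#' apply there; segments are atomic and are never trimmed to the PAR
#' boundary). Y-chromosome segments are classified `not_cnv` and excluded
#' throughout.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param sex per-segment sex of the carrying sample (recycled if length 1).
#' @param genome a [genome_model()].
#' @return character vector, one of `"not_cnv"`, `"autosomal_cnv"`,
#'   `"x_male_cnv"`, `"x_female_cnv"`, `"par_excluded"` per segment.
#' @export
classify_segments <- function(segments, sex, genome = default_genome()) {
  n <- nrow(segments)
  if (length(sex) == 1) sex <- rep(sex, n)
  stopifnot(length(sex) == n)
  chrom_length(segments$chrom, genome)  # validates chromosome membership
  cls <- rep("not_cnv", n)
  auto <- is_autosome(segments$chrom, genome)
  on_x <- segments$chrom == genome$x_chrom
  if (any(on_x & sex == "unknown")) {
    stop("sex must be known to classify X-chromosome segments")
  }
  cn <- segments$copy_number
  cls[auto & cn != 2] <- "autosomal_cnv"
  xm <- on_x & sex == "male"
  in_par <- intersects_par(segments$chrom, segments$start, segments$end,
                           genome)
  cls[xm & in_par] <- "par_excluded"
  cls[xm & !in_par & cn != 1] <- "x_male_cnv"
  xf <- on_x & sex == "female"
  cls[xf & cn != 2] <- "x_female_cnv"
  cls
}

#' Loss/gain direction of segments
#'
#' Direction is judged against the same expected ploidy as
#' [classify_segments()]: copy number below it is a `loss`, above it a
#' `gain`, equal to it (or PAR-excluded / Y) `none`. On the male non-PAR X
#' the baseline is one copy, so a male X segment at two copies is a gain.
#'
#' @inheritParams classify_segments
#' @return character vector of `"loss"`, `"gain"`, `"none"`.
#' @export
direction_of <- function(segments, sex, genome = default_genome()) {
  n <- nrow(segments)
  if (length(sex) == 1) sex <- rep(sex, n)
  cls <- classify_segments(segments, sex, genome)
  ploidy <- ifelse(cls == "x_male_cnv", 1, 2)
  dir <- rep("none", n)
  is_cnv <- cls %in% c("autosomal_cnv", "x_male_cnv", "x_female_cnv")
  dir[is_cnv & segments$copy_number < ploidy] <- "loss"
  dir[is_cnv & segments$copy_number > ploidy] <- "gain"
  dir
}

#' Size bin of segments
#'
#' @inheritParams classify_segments
#' @param config a [size_bin_config()].
#' @return character vector of `"sub_threshold"`, `"small"`, `"large"`.
#' @export
size_bin <- function(segments, config = size_bin_config()) {
  len <- segments$end - segments$start
  ifelse(len <= config$min_size, "sub_threshold",
         ifelse(len <= config$large_threshold, "small", "large"))
}
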