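#' Build a 2x2 size-stratified burden table
#'
#' Counts CNV segments (not carriers) longer than `bins$min_size` in two
#' sample groups, split into large (`> large_threshold`) and small cells.
#' Segments enter a stratum through [classify_segments()]: `autosomes`
#' collects `autosomal_cnv` segments, `x_male` / `x_female` the
#' corresponding X classes; PAR-excluded, Y and ploidy-neutral segments
#' never count. An optional direction filter restricts to losses or gains
#' as judged by [direction_of()].
#'
#' @param segments a `cnv_segments` data.frame (ideally after
#'   [apply_qc()]).
#' @param samples a `sample_sheet`; only listed samples contribute.
#' @param stratum `"autosomes"`, `"x_male"` or `"x_female"`.
#' @param direction_filter `"all"`, `"loss"` or `"gain"`.
#' @param bins a [size_bin_config()].
#' @param groups length-2 character vector naming the two status groups,
#'   group1 first (e.g. `c("case", "control")`).
#' @param genome a [genome_model()].
#' @return a list of class `burden_table` with cells `a` (large, group1),
#'   `b` (small, group1), `c` (large, group2), `d` (small, group2).
#' @export
build_burden_table <- function(segments, samples,
                               stratum = c("autosomes", "x_male", "x_female"),
                               direction_filter = c("all", "loss", "gain"),
                               bins = size_bin_config(),
                               groups = c("case", "control"),
                               genome = default_genome()) {
  stratum <- match.arg(stratum)
  direction_filter <- match.arg(direction_filter)
  stopifnot(length(groups) == 2)
  samples <- validate_samples(as.data.frame(samples))
  if (stratum == "x_male" && !any(samples$sex == "male")) {
    stop("stratum x_male requested but no male samples present")
  }
  if (stratum == "x_female" && !any(samples$sex == "female")) {
    stop("stratum x_female requested but no female samples present")
  }

  idx <- match(segments$sample_id, samples$sample_id)
  keep <- !is.na(idx)
  segments <- segments[keep, , drop = FALSE]
  idx <- idx[keep]
  sex <- samples$sex[idx]
  status <- samples$status[idx]

  target_class <- c(autosomes = "autosomal_cnv", x_male = "x_male_cnv",
                    x_female = "x_female_cnv")[[stratum]]
  cls <- if (nrow(segments)) classify_segments(segments, sex, genome)
         else character()
  keep <- cls == target_class
  if (direction_filter != "all") {
    dir <- if (nrow(segments)) direction_of(segments, sex, genome)
           else character()
    keep <- keep & dir == direction_filter
  }
  segments <- segments[keep, , drop = FALSE]
  status <- status[keep]

  bin <- size_bin(segments, bins)
  cell <- function(group, size) {
    sum(status == group & bin == size)
  }
  structure(
    list(stratum = stratum, direction_filter = direction_filter,
         a = cell(groups[1], "large"), b = cell(groups[1], "small"),
         c = cell(groups[2], "large"), d = cell(groups[2], "small"),
         group1 = groups[1], group2 = groups[2], bins = bins),
    class = "burden_table"
  )
}

#' Assemble a burden table from known cell counts
#'
#' Convenience constructor for working directly from published contingency
#' counts: `a`/`b` are the large/small segment counts in group 1, `c`/`d`
#' in group 2.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param stratum,direction_filter,group1,group2 labels carried along.
#' @return a `burden_table`.
#' @export
burden_table <- function(a, b, c, d, stratum = "autosomes",
                         direction_filter = "all",
                         group1 = "case", group2 = "control") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(stratum = stratum, direction_filter = direction_filter,
                 a = a, b = b, c = c, d = d,
                 group1 = group1, group2 = group2,
                 bins = size_bin_config()),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat(sprintf("burden_table [%s, %s]\n", x$stratum, x$direction_filter))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c(x$group1, x$group2), c("large", "small")))
  print(m)
  invisible(x)
}

#' Unconditional sample odds ratio of a 2x2 table
#'
#' The cross-product ratio `(a/b) / (c/d)`. With any zero cell the ratio is
#' undefined (or degenerately 0/Inf); the default policy flags it as `NA`
#' with attribute `flag = "undefined"`, while `zero_policy = "haldane"`
#' applies the Haldane-Anscombe correction (add 0.5 to every cell) first.
#'
#' @param table a `burden_table` (or any list with cells `a`, `b`, `c`,
#'   `d`).
#' @param zero_policy `"undefined"` (default) or `"haldane"`.
#' @return the odds ratio; `NA` with a `flag` attribute when undefined.
#' @export
sample_odds_ratio <- function(table, zero_policy = c("undefined", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) == 0)) {
    if (zero_policy == "undefined") {
      return(structure(NA_real_, flag = "undefined"))
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / b) / (c / d)
}

#' Exact hypergeometric p-value of a 2x2 table
#'
#' Fisher's exact test: with all margins fixed, the large-segment count of
#' group 1 follows a hypergeometric law, and the p-value is the exact tail
#' probability. `alternative = "greater"` returns `P(X >= a)` (enrichment
#' of large segments in group 1, i.e. odds ratio > 1), `"less"` returns
#' `P(X <= a)`, and `"two_sided"` sums the probabilities of all tables
#' whose point mass does not exceed that of the observed table (the
#' "minimum-likelihood" rule, as in [stats::fisher.test()]).
#'
#' @inheritParams sample_odds_ratio
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(table,
                           alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + c          # total large
  n <- b + d          # total small
  k <- a + b          # group-1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- switch(alternative,
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]),
    two_sided = {
      # relative tolerance guards ties against floating-point noise
      obs <- stats::dhyper(a, m, n, k)
      sum(dens[dens <= obs * (1 + 1e-7)])
    }
  )
  min(1, p)
}

#' Size-stratified CNV burden analysis
#'
#' Runs one exact one-sided (by default) burden test per requested
#' (stratum, direction) combination and applies a Bonferroni correction
#' across the tests actually performed in the run:
#' `bonferroni_threshold = alpha / n_tests`. A result is flagged
#' significant when its p-value is below that threshold.
#'
#' @inheritParams build_burden_table
#' @param strata character vector of strata to test.
#' @param direction_filters character vector of direction filters; the
#'   analysis crosses every stratum with every filter.
#' @param alpha family-wise error level (default 0.05).
#' @param alternative passed to [fisher_exact_p()].
#' @param zero_policy passed to [sample_odds_ratio()].
#' @return data.frame with one row per test: stratum, direction, the four
#'   cells, odds ratio, p-value, Bonferroni threshold and significance,
#'   ordered by (stratum, direction) as requested.
#' @export
burden_analysis <- function(segments, samples,
                            strata = c("autosomes", "x_male", "x_female"),
                            direction_filters = "all",
                            alpha = 0.05,
                            bins = size_bin_config(),
                            groups = c("case", "control"),
                            alternative = "greater",
                            zero_policy = "undefined",
                            genome = default_genome()) {
  combos <- expand.grid(direction = direction_filters, stratum = strata,
                        stringsAsFactors = FALSE)
  combos <- combos[order(match(combos$stratum, strata),
                         match(combos$direction, direction_filters)), ]
  n_tests <- nrow(combos)
  threshold <- alpha / n_tests
  rows <- lapply(seq_len(n_tests), function(i) {
    tab <- build_burden_table(segments, samples,
                              stratum = combos$stratum[i],
                              direction_filter = combos$direction[i],
                              bins = bins, groups = groups, genome = genome)
    p <- fisher_exact_p(tab, alternative)
    or <- sample_odds_ratio(tab, zero_policy)
    data.frame(stratum = tab$stratum, direction = tab$direction_filter,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               odds_ratio = as.numeric(or), p_value = p,
               bonferroni_threshold = threshold,
               significant = p < threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
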