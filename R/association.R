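#' Filter segments for association testing
#'
#' Only well-supported segments define pseudo-markers: a segment must rest
#' on at least `min_markers` array markers and span `min_span` bp or more
#' (both bounds inclusive).
#'
#' @param segments a `cnv_segments` data.frame.
#' @param min_markers minimum marker support (default 5).
#' @param min_span minimum length in bp (default 10,000, inclusive).
#' @return the qualifying subset, input order preserved.
#' @export
filter_for_association <- function(segments, min_markers = 5,
                                   min_span = 10000) {
  if (nrow(segments) == 0) return(segments)
  if (min_markers > 0 && anyNA(segments$n_markers)) {
    i <- which(is.na(segments$n_markers))[1]
    stop("segment without n_markers cannot be marker-filtered: sample ",
         segments$sample_id[i], " ", segments$chrom[i], ":",
         segments$start[i], "-", segments$end[i])
  }
  len <- segments$end - segments$start
  keep <- len >= min_span
  if (min_markers > 0) keep <- keep & segments$n_markers >= min_markers
  segments[keep, , drop = FALSE]
}

#' Build breakpoint pseudo-markers
#'
#' Every start and end point of a qualifying segment defines a test
#' position; one pseudo-marker exists per unique (chrom, position,
#' direction). A sample carries a marker when it has a segment of the same
#' direction whose half-open interval contains the position — with
#' end-breakpoints evaluated at `position - 1`, so a segment always carries
#' both of its own breakpoints. The union of the two rules is closed
#' containment `start <= position <= end`, which is how it is computed.
#'
#' @param segments filtered `cnv_segments` (see
#'   [filter_for_association()]).
#' @param samples a `sample_sheet`; supplies the sex used to call
#'   direction.
#' @param genome a [genome_model()].
#' @return data.frame sorted by (chrom, position, direction) with columns
#'   `chrom`, `position`, `direction` and a list-column `carriers` of
#'   sample-id character vectors.
#' @export
build_pseudomarkers <- function(segments, samples,
                                genome = default_genome()) {
  empty <- data.frame(chrom = character(), position = numeric(),
                      direction = character())
  empty$carriers <- list()
  if (nrow(segments) == 0) return(empty)
  sex <- samples$sex[match(segments$sample_id, samples$sample_id)]
  dir <- direction_of(segments, sex, genome)
  segments <- segments[dir != "none", , drop = FALSE]
  dir <- dir[dir != "none"]
  if (nrow(segments) == 0) return(empty)

  out <- list()
  for (key in unique(paste(segments$chrom, dir))) {
    sel <- paste(segments$chrom, dir) == key
    seg <- segments[sel, , drop = FALSE]
    positions <- sort(unique(c(seg$start, seg$end)))
    # closed containment via 1-based inclusive ranges
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = positions + 1, width = 1),
      IRanges::IRanges(start = seg$start + 1, end = seg$end + 1)
    )
    carriers <- lapply(seq_along(positions), function(i) {
      sort(unique(seg$sample_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]))
    })
    df <- data.frame(chrom = seg$chrom[1], position = positions,
                     direction = dir[sel][1])
    df$carriers <- carriers
    out[[key]] <- df
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$position, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

restore_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' One-sided permutation test of carrier enrichment in cases
#'
#' The statistic is the number of case samples carrying the marker. Under
#' the null, case labels are exchangeable, so labels are permuted with the
#' case count fixed. In `monte_carlo` mode `n_perm` uniform permutations
#' are drawn and the empirical p-value uses the +1 correction
#' `(1 + #{T_perm >= T_obs}) / (1 + n_perm)`, whose floor at 100,000
#' permutations is 1/100,001. In `exhaustive` mode all label assignments
#' with the same case count are enumerated and the exact tail fraction is
#' returned (equal to the one-sided hypergeometric tail).
#'
#' @param carriers character vector of carrying sample ids.
#' @param labels named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param mode `"monte_carlo"` (default) or `"exhaustive"`.
#' @return list with `empirical_p`, `observed` (case carrier count),
#'   `n_permutations`, `mode`.
#' @export
permutation_test <- function(carriers, labels, n_perm = 100000,
                             seed = NULL,
                             mode = c("monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(all(carriers %in% names(labels)))
  carrier_vec <- names(labels) %in% carriers
  is_case <- labels == "case"
  n <- length(labels)
  n_case <- sum(is_case)
  t_obs <- sum(carrier_vec & is_case)

  if (mode == "exhaustive") {
    n_assign <- choose(n, n_case)
    if (n_assign > 1e6) {
      stop("exhaustive enumeration over ", format(n_assign, big.mark = ","),
           " assignments is infeasible; use mode = 'monte_carlo'")
    }
    combos <- utils::combn(n, n_case)
    t_all <- colSums(matrix(carrier_vec[combos], nrow = n_case))
    p <- sum(t_all >= t_obs) / n_assign
    return(list(empirical_p = p, observed = t_obs,
                n_permutations = n_assign, mode = "exhaustive"))
  }

  stopifnot(n_perm >= 1)
  if (!is.null(seed)) {
    on.exit(restore_rng()())
    set.seed(seed)
  }
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (sum(carrier_vec[sample.int(n, n_case)]) >= t_obs) {
      exceed <- exceed + 1L
    }
  }
  list(empirical_p = (1 + exceed) / (1 + n_perm), observed = t_obs,
       n_permutations = n_perm, mode = "monte_carlo")
}

#' Carrier odds ratio
#'
#' Cross-product odds ratio of carrying versus not carrying a locus in
#' cases against controls.
#'
#' @param case_carriers,n_cases,control_carriers,n_controls counts.
#' @param zero_policy as in [sample_odds_ratio()].
#' @return the odds ratio, or flagged `NA`.
#' @examples
#' carrier_odds_ratio(43, 70, 103, 605)  # 7.76
#' @export
carrier_odds_ratio <- function(case_carriers, n_cases, control_carriers,
                               n_controls,
                               zero_policy = c("undefined", "haldane")) {
  stopifnot(case_carriers <= n_cases, control_carriers <= n_controls)
  sample_odds_ratio(
    list(a = case_carriers, b = n_cases - case_carriers,
         c = control_carriers, d = n_controls - control_carriers),
    zero_policy
  )
}

# deterministic per-marker seed below 2^31, mixed from the master seed and
# the marker identity so results do not depend on traversal order
marker_seed <- function(master, chrom, position, direction) {
  m <- 2147483647
  h <- master %% m
  for (ch in utf8ToInt(paste0(chrom, ":", direction))) {
    h <- (h * 31 + ch) %% m
  }
  h <- (h * 2654435761 + position) %% m
  as.integer(h)
}

#' Genome-wide pseudo-marker association scan
#'
#' Builds pseudo-markers from the filtered segments, tests each with the
#' one-sided permutation test (losses and gains separately throughout,
#' with the X chromosome analysed per sex when `sex_stratify_x`), then
#' merges maximal runs of consecutive significant markers on one
#' chromosome that share direction and an identical carrier set into one
#' locus spanning first to last breakpoint. Each marker's permutation
#' stream is seeded from (`seed`, chrom, position, direction), so merged
#' markers may carry slightly different Monte-Carlo p-values; the locus
#' reports the smallest.
#'
#' @param segments a `cnv_segments` data.frame (pre-QC'd cohort).
#' @param samples a `sample_sheet` with case/control status.
#' @param n_perm permutations per marker.
#' @param seed master seed.
#' @param threshold significance threshold on the empirical p (default
#'   5e-5); a marker is significant when `empirical_p <= threshold`.
#' @param sex_stratify_x analyse X-chromosome markers separately per sex.
#' @param min_markers,min_span passed to [filter_for_association()].
#' @param mode permutation mode, as in [permutation_test()].
#' @param genome a [genome_model()].
#' @return list with `loci` (merged significant loci sorted by chrom and
#'   start: interval, direction, carrier counts, group sizes, empirical p,
#'   carrier OR) and `markers` (every tested pseudo-marker with its p).
#' @export
associate <- function(segments, samples, n_perm = 100000, seed = 1,
                      threshold = 5e-5, sex_stratify_x = TRUE,
                      min_markers = 5, min_span = 10000,
                      mode = "monte_carlo", genome = default_genome()) {
  samples <- validate_samples(as.data.frame(samples))
  segments <- filter_for_association(segments, min_markers, min_span)

  analysis_sets <- list()
  on_x <- segments$chrom == genome$x_chrom
  if (sex_stratify_x) {
    analysis_sets$autosomal <- list(
      segments = segments[!on_x, , drop = FALSE], samples = samples)
    for (sx in c("male", "female")) {
      smp <- samples[samples$sex == sx, , drop = FALSE]
      seg <- segments[on_x & segments$sample_id %in% smp$sample_id, ,
                      drop = FALSE]
      if (nrow(seg)) analysis_sets[[paste0("x_", sx)]] <-
        list(segments = seg, samples = smp)
    }
  } else {
    analysis_sets$all <- list(segments = segments, samples = samples)
  }

  marker_rows <- list()
  for (set_name in names(analysis_sets)) {
    set <- analysis_sets[[set_name]]
    if (nrow(set$segments) == 0) next
    pm <- build_pseudomarkers(set$segments, set$samples, genome)
    if (nrow(pm) == 0) next
    labels <- stats::setNames(
      ifelse(set$samples$status %in% c("case", "affected"),
             "case", "control"),
      set$samples$sample_id)
    n_cases <- sum(labels == "case")
    n_controls <- sum(labels == "control")
    res <- lapply(seq_len(nrow(pm)), function(i) {
      pt <- permutation_test(
        pm$carriers[[i]], labels, n_perm = n_perm,
        seed = marker_seed(seed, pm$chrom[i], pm$position[i],
                           pm$direction[i]),
        mode = mode)
      data.frame(chrom = pm$chrom[i], position = pm$position[i],
                 direction = pm$direction[i], analysis = set_name,
                 case_carriers = pt$observed,
                 control_carriers = length(pm$carriers[[i]]) - pt$observed,
                 n_cases = n_cases, n_controls = n_controls,
                 empirical_p = pt$empirical_p,
                 n_permutations = pt$n_permutations, mode = pt$mode)
    })
    mk <- do.call(rbind, res)
    mk$carriers <- pm$carriers
    marker_rows[[set_name]] <- mk
  }

  empty_loci <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    direction = character(), analysis = character(),
    case_carriers = integer(), control_carriers = integer(),
    n_cases = integer(), n_controls = integer(), empirical_p = numeric(),
    carrier_or = numeric(), n_permutations = numeric(), mode = character())
  empty_markers <- data.frame(
    chrom = character(), position = numeric(), direction = character(),
    analysis = character(), case_carriers = integer(),
    control_carriers = integer(), n_cases = integer(),
    n_controls = integer(), empirical_p = numeric(),
    n_permutations = numeric(), mode = character())
  if (length(marker_rows) == 0) {
    return(list(loci = empty_loci, markers = empty_markers))
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL

  sig <- markers[markers$empirical_p <= threshold & markers$case_carriers > 0,
                 , drop = FALSE]
  loci <- empty_loci
  if (nrow(sig)) {
    sig <- sig[order(sig$analysis, sig$chrom, sig$direction, sig$position), ,
               drop = FALSE]
    key <- vapply(seq_len(nrow(sig)), function(i) {
      paste(sig$analysis[i], sig$chrom[i], sig$direction[i],
            paste(sig$carriers[[i]], collapse = ","))
    }, character(1))
    run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    loci <- do.call(rbind, lapply(split(seq_len(nrow(sig)), run), function(ix) {
      s <- sig[ix, , drop = FALSE]
      or <- carrier_odds_ratio(s$case_carriers[1], s$n_cases[1],
                               s$control_carriers[1], s$n_controls[1])
      data.frame(chrom = s$chrom[1], start = min(s$position),
                 end = max(s$position), direction = s$direction[1],
                 analysis = s$analysis[1],
                 case_carriers = s$case_carriers[1],
                 control_carriers = s$control_carriers[1],
                 n_cases = s$n_cases[1], n_controls = s$n_controls[1],
                 empirical_p = min(s$empirical_p),
                 carrier_or = as.numeric(or),
                 n_permutations = s$n_permutations[1], mode = s$mode[1])
    }))
    loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
    rownames(loci) <- NULL
  }
  markers$carriers <- NULL
  list(loci = loci, markers = markers)
}

#' Format a p-value the way association tables print it
#'
#' Scientific notation with one decimal digit and no zero-padded exponent,
#' e.g. `1.0E-5`; values at or above 0.001 print as plain decimals.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 1e-3) return(format(signif(x, 2), scientific = FALSE))
    s <- sprintf("%.1E", x)
    sub("E([+-])0*(\\d)", "E\\1\\2", s)
  }, character(1))
}

#' Round half away from zero
#'
#' Unlike [round()], which rounds half to even, ties move away from zero:
#' `round_half_away(56.625, 2)` is 56.63. This is the convention used when
#' printing odds ratios in reports.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
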