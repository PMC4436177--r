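#' Simulation configuration for synthetic CNV cohorts
#'
#' Collects every knob of [simulate_cohort()] with defaults that emulate a
#' rare-CNV case-control study at configurable scale: negative-binomial
#' per-sample autosomal segment counts, log-normal segment lengths
#' truncated below (heavy right tail, a minority of segments above
#' 100 kb), per-sex X-chromosome segment counts, an odds multiplier
#' `x_large_enrichment_or` acting on the probability that a male *case* X
#' segment exceeds the large-size threshold (the exact quantity the
#' size-binned burden test measures), optional planted case-enriched loci
#' for association-recovery experiments, count-outlier samples for QC
#' testing, and pedigree specifications with planted shared segments.
#'
#' @param seed integer master seed.
#' @param n_case_male,n_case_female,n_control_male,n_control_female group
#'   sizes; defaults mirror a cohort of 70 cases (51 male) against 605
#'   controls with the same male fraction.
#' @param count_mean,count_dispersion negative-binomial mean and `size`
#'   for per-sample autosomal segment counts.
#' @param length_meanlog,length_sdlog log-normal parameters of segment
#'   length in bp.
#' @param length_floor lower truncation of segment length (bp).
#' @param x_count_mean expected X segments per sample.
#' @param x_large_enrichment_or odds multiplier for large male-case X
#'   segments (1 = null).
#' @param large_threshold bp threshold defining "large" for the
#'   enrichment mechanism (matches [size_bin_config()] default).
#' @param planted_loci data.frame with columns `chrom, start, end,
#'   direction, f_case, f_control, n_markers`, or NULL.
#' @param outlier_fraction,outlier_multiplier fraction of samples whose
#'   segment count is multiplied (QC targets).
#' @param marker_density markers per bp used to assign `n_markers` as
#'   `max(1, round(marker_density * length))`.
#' @param families list of family specs, each a list with `family_id`,
#'   `n_affected`, `n_unaffected`; used by [simulate_families()].
#' @param planted_family_locus list with `chrom, start, end, direction,
#'   jitter` for the duplication shared by all affected members.
#' @param genome a [genome_model()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_case_male = 51, n_case_female = 19,
                       n_control_male = 441, n_control_female = 164,
                       count_mean = 25, count_dispersion = 8,
                       length_meanlog = log(20000), length_sdlog = 1.1,
                       length_floor = 1000,
                       x_count_mean = 2,
                       x_large_enrichment_or = 1,
                       large_threshold = 100000,
                       planted_loci = NULL,
                       outlier_fraction = 0, outlier_multiplier = 4,
                       marker_density = 1 / 2000,
                       families = NULL,
                       planted_family_locus = NULL,
                       genome = default_genome()) {
  if (x_large_enrichment_or <= 0) stop("x_large_enrichment_or must be > 0")
  if (!is.null(planted_loci)) {
    stopifnot(all(c("chrom", "start", "end", "direction", "f_case",
                    "f_control", "n_markers") %in% names(planted_loci)))
    if (any(planted_loci$f_case < 0 | planted_loci$f_case > 1 |
            planted_loci$f_control < 0 | planted_loci$f_control > 1)) {
      stop("planted locus frequencies must lie in [0, 1]")
    }
    lens <- chrom_length(planted_loci$chrom, genome)
    if (any(planted_loci$end > lens) || any(planted_loci$start < 0)) {
      stop("planted locus outside genome bounds")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# length draw from the truncated log-normal; `side` forces the draw into
# the small (<= threshold) or large (> threshold) size class
draw_lengths <- function(n, cfg, side = c("any", "small", "large")) {
  side <- match.arg(side)
  lo <- cfg$length_floor
  thr <- cfg$large_threshold
  plo <- stats::plnorm(lo, cfg$length_meanlog, cfg$length_sdlog)
  pthr <- stats::plnorm(thr, cfg$length_meanlog, cfg$length_sdlog)
  u <- stats::runif(n)
  q <- switch(side,
    any = plo + u * (1 - plo),
    small = plo + u * (pthr - plo),
    large = pthr + u * (1 - pthr))
  round(stats::qlnorm(q, cfg$length_meanlog, cfg$length_sdlog))
}

# P(length > large_threshold) under the truncated base length model
base_large_prob <- function(cfg) {
  plo <- stats::plnorm(cfg$length_floor, cfg$length_meanlog,
                       cfg$length_sdlog)
  pthr <- stats::plnorm(cfg$large_threshold, cfg$length_meanlog,
                        cfg$length_sdlog)
  (1 - pthr) / (1 - plo)
}

# uniform placement of a segment of given length on a chromosome,
# avoiding PAR intersection on the male X when asked
place_segment <- function(chrom, len, genome, avoid_par = FALSE) {
  cl <- chrom_length(chrom, genome)
  len <- min(len, cl - 1)
  repeat {
    start <- floor(stats::runif(1, 0, cl - len))
    if (!avoid_par ||
        !intersects_par(chrom, start, start + len, genome)) {
      return(c(start, start + len))
    }
  }
}

#' Simulate a case-control CNV cohort
#'
#' Draws per-sample segment lists under the model described in
#' [sim_config()] and returns them alongside the sample sheet and a truth
#' table recording planted carriers, outlier samples and the configured
#' male-X enrichment. Autosomal background segments are placed uniformly
#' on autosomes chosen proportionally to length, with loss/gain decided by
#' a fair coin (copy number 1 or 3); X segments use copy numbers 0/2
#' (male, placed outside the PARs) and 1/3 (female). For male case X
#' segments the probability `p` of drawing a length in the large class is
#' tilted to odds `theta * p / (1 - p)`; all other samples use the base
#' model, so the population large-vs-small odds ratio between male cases
#' and male controls equals `theta` by construction.
#'
#' @param config a [sim_config()].
#' @return list with `segments` (a `cnv_segments`), `samples` (a
#'   `sample_sheet`), and `truth` (planted carrier memberships, outlier
#'   ids, configured enrichment and the base large-class probability).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  on.exit(restore_rng()())
  set.seed(config$seed)
  genome <- config$genome

  groups <- data.frame(
    status = rep(c("case", "case", "control", "control"),
                 c(config$n_case_male, config$n_case_female,
                   config$n_control_male, config$n_control_female)),
    sex = rep(c("male", "female", "male", "female"),
              c(config$n_case_male, config$n_case_female,
                config$n_control_male, config$n_control_female)))
  n <- nrow(groups)
  samples <- sample_sheet(sprintf("S%04d", seq_len(n)),
                          groups$sex, groups$status)

  autosomes <- genome$chromosomes$chrom[
    is_autosome(genome$chromosomes$chrom, genome)]
  auto_weights <- genome$chromosomes$length[
    match(autosomes, genome$chromosomes$chrom)]

  outliers <- character()
  if (config$outlier_fraction > 0) {
    n_out <- max(1, round(config$outlier_fraction * n))
    outliers <- sample(samples$sample_id, n_out)
  }

  p0 <- base_large_prob(config)
  theta <- config$x_large_enrichment_or
  p_case <- theta * p0 / (1 - p0 + theta * p0)

  seg_list <- list()
  for (i in seq_len(n)) {
    sid <- samples$sample_id[i]
    n_auto <- stats::rnbinom(1, size = config$count_dispersion,
                             mu = config$count_mean)
    if (sid %in% outliers) n_auto <- n_auto * config$outlier_multiplier
    if (n_auto > 0) {
      chroms <- sample(autosomes, n_auto, replace = TRUE,
                       prob = auto_weights)
      lens <- draw_lengths(n_auto, config)
      gain <- stats::runif(n_auto) < 0.5
      pos <- t(vapply(seq_len(n_auto), function(j) {
        place_segment(chroms[j], lens[j], genome)
      }, numeric(2)))
      seg_list[[length(seg_list) + 1]] <- data.frame(
        sample_id = sid, chrom = chroms, start = pos[, 1], end = pos[, 2],
        copy_number = ifelse(gain, 3L, 1L))
    }
    n_x <- stats::rpois(1, config$x_count_mean)
    if (n_x > 0) {
      male <- samples$sex[i] == "male"
      p_large <- if (male && samples$status[i] == "case") p_case else p0
      large <- stats::runif(n_x) < p_large
      lens <- numeric(n_x)
      if (any(large)) lens[large] <- draw_lengths(sum(large), config,
                                                  "large")
      if (any(!large)) lens[!large] <- draw_lengths(sum(!large), config,
                                                    "small")
      gain <- stats::runif(n_x) < 0.5
      cn <- if (male) ifelse(gain, 2L, 0L) else ifelse(gain, 3L, 1L)
      pos <- t(vapply(seq_len(n_x), function(j) {
        place_segment(genome$x_chrom, lens[j], genome, avoid_par = male)
      }, numeric(2)))
      seg_list[[length(seg_list) + 1]] <- data.frame(
        sample_id = sid, chrom = genome$x_chrom,
        start = pos[, 1], end = pos[, 2], copy_number = cn)
    }
  }

  planted_truth <- list()
  if (!is.null(config$planted_loci)) {
    for (k in seq_len(nrow(config$planted_loci))) {
      pl <- config$planted_loci[k, ]
      f <- ifelse(samples$status == "case", pl$f_case, pl$f_control)
      carrier <- stats::runif(n) < f
      ids <- samples$sample_id[carrier]
      planted_truth[[k]] <- list(
        chrom = pl$chrom, start = pl$start, end = pl$end,
        direction = pl$direction, carriers = ids)
      if (length(ids)) {
        seg_list[[length(seg_list) + 1]] <- data.frame(
          sample_id = ids, chrom = pl$chrom, start = pl$start,
          end = pl$end,
          copy_number = if (pl$direction == "gain") 3L else 1L)
      }
    }
  }

  segments <- if (length(seg_list)) do.call(rbind, seg_list)
              else data.frame(sample_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              copy_number = integer())
  segments$n_markers <- pmax(
    1L, as.integer(round(config$marker_density *
                           (segments$end - segments$start))))
  # planted loci keep their configured marker support
  if (!is.null(config$planted_loci) && length(planted_truth)) {
    for (k in seq_along(planted_truth)) {
      pl <- config$planted_loci[k, ]
      hit <- segments$chrom == pl$chrom & segments$start == pl$start &
        segments$end == pl$end
      segments$n_markers[hit] <- as.integer(pl$n_markers)
    }
  }
  segments <- validate_segments(segments)
  list(segments = segments, samples = samples,
       truth = list(planted = planted_truth, outliers = sort(outliers),
                    x_large_enrichment_or = theta,
                    base_large_prob = p0))
}

#' Simulate pedigrees with a planted shared duplication
#'
#' Emits affected and unaffected members for each family in
#' `config$families`, gives every member background autosomal segments
#' from the cohort count/length model, and plants the segment described by
#' `config$planted_family_locus` in every affected member, with each
#' person's breakpoints independently jittered by up to `jitter` bp on
#' each side (uniform), so the region shared by all affecteds is the
#' intersection of the jittered copies.
#'
#' @param config a [sim_config()] with non-empty `families` and a
#'   `planted_family_locus`.
#' @return list of `segments`, `samples`, `truth` (the planted interval
#'   and per-person realized intervals).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$families) || length(config$families) == 0) {
    stop("config$families must be non-empty")
  }
  pl <- config$planted_family_locus
  if (!is.null(pl)) {
    jitter <- if (is.null(pl$jitter)) 0 else pl$jitter
    if (jitter > (pl$end - pl$start) / 2) {
      stop("jitter exceeds half the planted interval length")
    }
  }
  on.exit(restore_rng()())
  set.seed(config$seed + 101)
  genome <- config$genome
  autosomes <- genome$chromosomes$chrom[
    is_autosome(genome$chromosomes$chrom, genome)]
  auto_weights <- genome$chromosomes$length[
    match(autosomes, genome$chromosomes$chrom)]

  sample_rows <- list()
  for (fam in config$families) {
    stat <- rep(c("affected", "unaffected"),
                c(fam$n_affected, fam$n_unaffected))
    sample_rows[[fam$family_id]] <- data.frame(
      sample_id = sprintf("%s_%s%d", fam$family_id,
                          ifelse(stat == "affected", "A", "U"),
                          stats::ave(seq_along(stat), stat,
                                     FUN = seq_along)),
      sex = sample(c("male", "female"), length(stat), replace = TRUE),
      status = stat, family_id = fam$family_id)
  }
  samples <- validate_samples(do.call(rbind, sample_rows))
  rownames(samples) <- NULL

  seg_list <- list()
  for (i in seq_len(nrow(samples))) {
    n_auto <- stats::rnbinom(1, size = config$count_dispersion,
                             mu = config$count_mean)
    if (n_auto > 0) {
      chroms <- sample(autosomes, n_auto, replace = TRUE,
                       prob = auto_weights)
      lens <- draw_lengths(n_auto, config)
      gain <- stats::runif(n_auto) < 0.5
      pos <- t(vapply(seq_len(n_auto), function(j) {
        place_segment(chroms[j], lens[j], genome)
      }, numeric(2)))
      seg_list[[length(seg_list) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], chrom = chroms,
        start = pos[, 1], end = pos[, 2],
        copy_number = ifelse(gain, 3L, 1L))
    }
  }

  realized <- NULL
  if (!is.null(pl)) {
    affected <- samples$sample_id[samples$status == "affected"]
    jitter <- if (is.null(pl$jitter)) 0 else pl$jitter
    starts <- pl$start + if (jitter > 0)
      round(stats::runif(length(affected), -jitter, jitter)) else 0
    ends <- pl$end + if (jitter > 0)
      round(stats::runif(length(affected), -jitter, jitter)) else 0
    realized <- data.frame(sample_id = affected, chrom = pl$chrom,
                           start = starts, end = ends)
    seg_list[[length(seg_list) + 1]] <- data.frame(
      sample_id = affected, chrom = pl$chrom, start = starts, end = ends,
      copy_number = if (pl$direction == "gain") 3L else 1L)
  }

  segments <- do.call(rbind, seg_list)
  segments$n_markers <- pmax(
    1L, as.integer(round(config$marker_density *
                           (segments$end - segments$start))))
  segments <- validate_segments(segments)
  list(segments = segments, samples = samples,
       truth = list(planted_family_locus = pl, realized = realized))
}
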