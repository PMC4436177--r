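#' CNV regions shared among affected family members
#'
#' Sweep-line detection of intervals carried by at least `min_affected`
#' distinct affected individuals and by at most `max_unaffected` distinct
#' unaffected individuals, per chromosome and direction. Between two
#' consecutive breakpoints the set of covering samples is constant, so the
#' sweep evaluates the two carrier counts on each elementary interval and
#' concatenates maximal runs of qualifying intervals. A person counts once
#' however many of their segments overlap a position, and matching is
#' direction-specific: a gain and a loss never share a region.
#'
#' Only segments longer than `min_size` bp enter the sweep. Unaffected
#' relatives genotyped within the families are the comparison set; samples
#' with case/control status are ignored with a warning.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param samples a `sample_sheet` with affected/unaffected statuses and
#'   family ids.
#' @param min_affected minimum number of distinct affected carriers.
#' @param max_unaffected maximum tolerated distinct unaffected carriers
#'   (default 0).
#' @param direction `"gain"`, `"loss"` or `"both"` (default) — which
#'   segment directions to scan, each separately.
#' @param min_size bp floor; only segments with `length > min_size` are
#'   considered (default 10,000).
#' @param genome a [genome_model()].
#' @return data.frame sorted by (chrom, start): interval, direction,
#'   `n_affected` (the minimum distinct affected carrier count across the
#'   region), `n_unaffected` (the maximum across it), comma-joined
#'   `affected_ids`, `families_represented`, and a `support` label such as
#'   `"6/0"`.
#' @export
shared_regions <- function(segments, samples, min_affected,
                           max_unaffected = 0,
                           direction = c("both", "gain", "loss"),
                           min_size = 10000, genome = default_genome()) {
  direction <- match.arg(direction)
  samples <- validate_samples(as.data.frame(samples))
  familial <- samples$status %in% c("affected", "unaffected")
  if (!any(samples$status == "affected")) {
    stop("no affected samples in the sample sheet")
  }
  if (any(!familial)) {
    warning("ignoring ", sum(!familial),
            " sample(s) without affected/unaffected status")
    samples <- samples[familial, , drop = FALSE]
  }
  segments <- segments[segments$sample_id %in% samples$sample_id, ,
                       drop = FALSE]
  segments <- segments[(segments$end - segments$start) > min_size, ,
                       drop = FALSE]
  idx <- match(segments$sample_id, samples$sample_id)
  sex <- samples$sex[idx]
  seg_dir <- if (nrow(segments)) direction_of(segments, sex, genome)
             else character()
  affected_ids_all <- samples$sample_id[samples$status == "affected"]

  dirs <- if (direction == "both") c("gain", "loss") else direction
  out <- list()
  for (d in dirs) {
    seg <- segments[seg_dir == d, , drop = FALSE]
    if (nrow(seg) == 0) next
    for (chr in unique(seg$chrom)) {
      s <- seg[seg$chrom == chr, , drop = FALSE]
      bp <- sort(unique(c(s$start, s$end)))
      if (length(bp) < 2) next
      lo <- bp[-length(bp)]
      hi <- bp[-1]
      n_aff <- integer(length(lo))
      n_unaff <- integer(length(lo))
      cover_sets <- vector("list", length(lo))
      status_of <- stats::setNames(samples$status, samples$sample_id)
      for (i in seq_along(lo)) {
        covering <- unique(s$sample_id[s$start <= lo[i] & s$end >= hi[i]])
        cover_sets[[i]] <- covering
        n_aff[i] <- sum(status_of[covering] == "affected")
        n_unaff[i] <- sum(status_of[covering] == "unaffected")
      }
      ok <- n_aff >= min_affected & n_unaff <= max_unaffected
      if (!any(ok)) next
      run <- cumsum(c(TRUE, diff(ok) != 0))
      for (r in unique(run[ok])) {
        ix <- which(run == r & ok)
        aff_ids <- sort(unique(unlist(
          lapply(cover_sets[ix],
                 function(cs) cs[status_of[cs] == "affected"]))))
        fams <- unique(samples$family_id[match(aff_ids, samples$sample_id)])
        na_min <- min(n_aff[ix]); nu_max <- max(n_unaff[ix])
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = lo[min(ix)], end = hi[max(ix)],
          direction = d, n_affected = na_min, n_unaffected = nu_max,
          affected_ids = paste(aff_ids, collapse = ","),
          families_represented = length(fams),
          support = sprintf("%d/%d", na_min, nu_max))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_affected = integer(), n_unaffected = integer(),
                      affected_ids = character(),
                      families_represented = integer(),
                      support = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Overlaps between two region sets
#'
#' Pairs every region of one set with every same-chromosome,
#' same-direction region of the other that it intersects by at least
#' `min_bp` base pairs, reporting the intersection interval. Typical use:
#' checking whether loci found in a sporadic case-control scan coincide
#' with regions shared within families.
#'
#' @param regions_a,regions_b data.frames with columns `chrom`, `start`,
#'   `end` and optionally `direction` (matched when present in both).
#' @param min_bp minimum overlap in bp (default 1).
#' @return data.frame with one row per overlapping pair: indices into both
#'   inputs, chrom, direction, and the intersection interval with its
#'   width.
#' @export
cross_cohort_overlap <- function(regions_a, regions_b, min_bp = 1) {
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      chrom = character(), direction = character(),
                      start = numeric(), end = numeric(),
                      overlap_bp = numeric())
  if (nrow(regions_a) == 0 || nrow(regions_b) == 0) return(empty)
  match_dir <- "direction" %in% names(regions_a) &&
    "direction" %in% names(regions_b)
  rows <- list()
  for (i in seq_len(nrow(regions_a))) {
    for (j in seq_len(nrow(regions_b))) {
      if (regions_a$chrom[i] != regions_b$chrom[j]) next
      if (match_dir &&
          regions_a$direction[i] != regions_b$direction[j]) next
      s <- max(regions_a$start[i], regions_b$start[j])
      e <- min(regions_a$end[i], regions_b$end[j])
      if (e - s >= min_bp) {
        rows[[length(rows) + 1]] <- data.frame(
          idx_a = i, idx_b = j, chrom = regions_a$chrom[i],
          direction = if (match_dir) regions_a$direction[i]
                      else NA_character_,
          start = s, end = e, overlap_bp = e - s)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
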