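# Independent oracles and small fixture builders used across the suite.

# Tiny two-chromosome genome: one autosome and an X with a PAR at [0, 50).
toy_genome <- function() {
  genome_model(
    chromosomes = data.frame(chrom = c("chr1", "chrX"),
                             length = c(1e6, 5e5)),
    par_intervals = data.frame(chrom = "chrX", start = 0, end = 50)
  )
}

# Brute-force hypergeometric tail from binomial coefficients only; never
# touches dhyper or the package implementation.
oracle_fisher_p <- function(a, b, c, d,
                            alternative = c("greater", "less",
                                            "two_sided")) {
  alternative <- match.arg(alternative)
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  support <- max(0, k - n):min(k, m)
  mass <- exp(lchoose(m, support) + lchoose(n, k - support) -
                lchoose(N, k))
  p <- switch(alternative,
    greater = sum(mass[support >= a]),
    less = sum(mass[support <= a]),
    two_sided = sum(mass[mass <= mass[support == a] * (1 + 1e-7)]))
  min(1, p)
}

# Per-base-pair brute force for shared regions: classifies every integer
# position on the (small) toy range by direct coverage counting, then
# stitches qualifying positions into maximal intervals.
oracle_shared_regions <- function(segments, samples, min_affected,
                                  max_unaffected, direction) {
  status_of <- stats::setNames(samples$status, samples$sample_id)
  seg <- segments[segments$direction == direction, , drop = FALSE]
  out <- list()
  for (chr in sort(unique(seg$chrom))) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    positions <- seq(min(s$start), max(s$end) - 1)
    ok <- logical(length(positions))
    for (pi in seq_along(positions)) {
      p <- positions[pi]
      covering <- unique(s$sample_id[s$start <= p & s$end > p])
      n_aff <- sum(status_of[covering] == "affected")
      n_unaff <- sum(status_of[covering] == "unaffected")
      ok[pi] <- n_aff >= min_affected && n_unaff <= max_unaffected
    }
    if (!any(ok)) next
    run <- cumsum(c(TRUE, diff(ok) != 0 | diff(positions) != 1))
    for (r in unique(run[ok])) {
      ix <- which(run == r & ok)
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = positions[min(ix)],
        end = positions[max(ix)] + 1, direction = direction)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Quadratic all-pairs interval annotation oracle.
oracle_annotate <- function(regions, genes, mode) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- character()
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != regions$chrom[i]) next
      ov <- min(regions$end[i], genes$end[j]) -
        max(regions$start[i], genes$start[j])
      inside <- genes$start[j] >= regions$start[i] &&
        genes$end[j] <= regions$end[i]
      if ((mode == "any_overlap" && ov >= 1) ||
          (mode == "containment" && inside)) {
        hits <- c(hits, genes$symbol[j])
      }
    }
    sort(hits)
  })
}

# Random familial segment instance on small coordinates for oracle
# comparisons; returns segments annotated with a direction column.
random_family_instance <- function(n_segments, n_samples = 8) {
  ids <- sprintf("P%02d", seq_len(n_samples))
  status <- rep(c("affected", "unaffected"), length.out = n_samples)
  samples <- sample_sheet(ids, "female", status,
                          family_id = rep(c("F1", "F2"),
                                          length.out = n_samples))
  start <- sample.int(350, n_segments, replace = TRUE)
  len <- 11 + sample.int(40, n_segments, replace = TRUE)
  seg <- cnv_segments(sample(ids, n_segments, replace = TRUE), "chr1",
                      start, start + len,
                      sample(c(1L, 3L), n_segments, replace = TRUE), 5L)
  seg$direction <- ifelse(seg$copy_number == 3L, "gain", "loss")
  list(segments = seg, samples = samples)
}
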