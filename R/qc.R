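#' Segment-count QC cutoff
#'
#' The per-cohort exclusion cutoff is the median segment count plus the
#' spread between the median and the minimum: `2 * median(counts) -
#' min(counts)`. For an even number of samples the median is the midpoint
#' of the central pair, so the cutoff may be non-integer.
#'
#' @param counts non-negative integer vector of per-sample segment counts.
#' @return the cutoff (numeric scalar).
#' @examples
#' qc_cutoff(c(2, 3, 3, 4, 10))  # median 3, min 2 -> 4
#' @export
qc_cutoff <- function(counts) {
  if (length(counts) == 0) stop("counts must be non-empty")
  2 * stats::median(counts) - min(counts)
}

#' Apply segment-count sample QC per cohort
#'
#' Samples calling unusually many CNV segments are array-quality suspects
#' and are removed before burden testing. Within each cohort group
#' (by default the case/control or affected/unaffected status groups) the
#' cutoff of [qc_cutoff()] is computed from all samples' segment counts,
#' and samples with strictly more segments than the cutoff are excluded.
#' Groups are never pooled: each group gets its own median, minimum and
#' cutoff. Counts include every segment attributed to a sample, regardless
#' of size, unless `min_size` is given, in which case only segments longer
#' than `min_size` bp are counted. Samples with no segments count zero.
#' QC is a single pass: the cutoff is not recomputed after exclusion.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param samples a `sample_sheet` data.frame covering every segment's
#'   sample.
#' @param group_by sample-sheet column defining the cohorts (default
#'   `"status"`).
#' @param min_size optional bp floor; count only segments with
#'   `length > min_size`.
#' @return a list with `samples` (the retained sample sheet) and `reports`,
#'   one entry per cohort with fields `cohort_label`, `per_sample_counts`,
#'   `median`, `minimum`, `cutoff`, `excluded`.
#' @export
apply_qc <- function(segments, samples, group_by = "status",
                     min_size = NULL) {
  samples <- validate_samples(as.data.frame(samples))
  unknown <- setdiff(unique(segments$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop("segments reference sample(s) absent from the sample sheet: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!is.null(min_size)) {
    segments <- segments[(segments$end - segments$start) > min_size, ,
                         drop = FALSE]
  }
  tab <- table(factor(segments$sample_id, levels = samples$sample_id))
  counts <- as.integer(tab)
  names(counts) <- samples$sample_id

  groups <- split(samples$sample_id, samples[[group_by]])
  reports <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    cts <- counts[ids]
    cut <- qc_cutoff(cts)
    list(cohort_label = g,
         per_sample_counts = cts,
         median = stats::median(cts),
         minimum = min(cts),
         cutoff = cut,
         excluded = ids[cts > cut])
  })
  names(reports) <- names(groups)
  excluded <- unlist(lapply(reports, `[[`, "excluded"), use.names = FALSE)
  list(samples = samples[!samples$sample_id %in% excluded, , drop = FALSE],
       reports = reports)
}

#' Write a QC report
#'
#' Emits one TSV row per cohort (label, n, median, minimum, cutoff,
#' comma-separated excluded ids) and, if `json_path` is given, the full
#' report including per-sample counts as JSON.
#'
#' @param qc result of [apply_qc()].
#' @param path TSV output path.
#' @param json_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path, json_path = NULL) {
  rows <- do.call(rbind, lapply(qc$reports, function(r) {
    data.frame(cohort = r$cohort_label,
               n_samples = length(r$per_sample_counts),
               median = r$median, minimum = r$minimum, cutoff = r$cutoff,
               n_excluded = length(r$excluded),
               excluded = paste(r$excluded, collapse = ","))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(qc$reports, function(r) {
        list(cohort = r$cohort_label,
             per_sample_counts = as.list(r$per_sample_counts),
             median = r$median, minimum = r$minimum, cutoff = r$cutoff,
             excluded = r$excluded)
      }),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
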