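#' End-to-end CNV analysis pipeline
#'
#' Orchestrates the analysis stages on one cohort: sample QC
#' ([apply_qc()]), size-stratified burden testing ([burden_analysis()]),
#' pseudo-marker permutation association ([associate()]), familial shared
#' regions ([shared_regions()], run only when the sample sheet contains
#' affected/unaffected members), and gene annotation of the association
#' loci ([annotate_regions()], run only when a gene table is supplied).
#' Each stage writes a TSV into `out_dir` topped by provenance comment
#' lines (package version, seed, parameters). Inputs are never modified;
#' stages communicate through in-memory tables.
#'
#' @param segments a `cnv_segments` data.frame, or a path readable by
#'   [read_segments()].
#' @param samples a `sample_sheet` data.frame, or a path readable by
#'   [read_samples()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed for the association permutations.
#' @param n_perm permutations per pseudo-marker.
#' @param genes optional gene data.frame (see [read_genes()]) or path to a
#'   BED4 gene list; required if `annotate = TRUE`.
#' @param annotate whether to annotate association loci with genes.
#' @param alpha family-wise level for the burden Bonferroni correction.
#' @param assoc_threshold association significance threshold.
#' @param bins a [size_bin_config()].
#' @param min_affected familial sharing threshold (only used when
#'   pedigree samples are present).
#' @param genome a [genome_model()].
#' @return invisibly, a list with each stage's in-memory result and the
#'   paths written.
#' @export
run_pipeline <- function(segments, samples, out_dir, seed = 1,
                         n_perm = 10000, genes = NULL, annotate = !is.null(genes),
                         alpha = 0.05, assoc_threshold = 5e-5,
                         bins = size_bin_config(), min_affected = 2,
                         genome = default_genome()) {
  if (annotate && is.null(genes)) {
    stop("annotation requested but no gene list supplied")
  }
  if (is.character(segments)) segments <- read_segments(segments)
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(genes)) genes <- read_genes(genes)
  samples <- validate_samples(as.data.frame(samples))
  segments <- validate_segments(as.data.frame(segments))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  provenance <- c(
    sprintf("# cnvcc %s", as.character(utils::packageVersion("cnvcc"))),
    sprintf("# seed: %d", seed),
    sprintf("# n_perm: %d | alpha: %g | assoc_threshold: %g", n_perm,
            alpha, assoc_threshold),
    sprintf("# bins: min_size=%g large_threshold=%g", bins$min_size,
            bins$large_threshold))
  write_stage <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(provenance, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    path
  }

  paths <- list()
  message(sprintf("[qc] %d segments across %d samples", nrow(segments),
                  nrow(samples)))
  qc <- apply_qc(segments, samples)
  seg_qc <- segments[segments$sample_id %in% qc$samples$sample_id, ,
                     drop = FALSE]
  paths$qc <- file.path(out_dir, "qc.tsv")
  write_qc_report(qc, paths$qc, file.path(out_dir, "qc.json"))
  message(sprintf("[qc] retained %d samples / %d segments",
                  nrow(qc$samples), nrow(seg_qc)))

  is_cc <- qc$samples$status %in% c("case", "control")
  burden <- NULL
  if (any(is_cc)) {
    cc_samples <- qc$samples[is_cc, , drop = FALSE]
    strata <- c("autosomes",
                if (any(cc_samples$sex == "male")) "x_male",
                if (any(cc_samples$sex == "female")) "x_female")
    burden <- burden_analysis(seg_qc, cc_samples, strata = strata,
                              alpha = alpha, bins = bins, genome = genome)
    paths$burden <- write_stage(burden, "burden")
    message(sprintf("[burden] %d tests, threshold %.4g", nrow(burden),
                    burden$bonferroni_threshold[1]))
  }

  assoc <- NULL
  if (any(is_cc)) {
    assoc <- associate(seg_qc, qc$samples[is_cc, , drop = FALSE],
                       n_perm = n_perm, seed = seed,
                       threshold = assoc_threshold, genome = genome)
    paths$association <- write_stage(assoc$loci, "association")
    message(sprintf("[assoc] %d pseudo-markers tested, %d loci",
                    nrow(assoc$markers), nrow(assoc$loci)))
  }

  familial <- NULL
  if (any(qc$samples$status %in% c("affected", "unaffected"))) {
    fam_samples <- qc$samples[
      qc$samples$status %in% c("affected", "unaffected"), , drop = FALSE]
    fam_segments <- seg_qc[
      seg_qc$sample_id %in% fam_samples$sample_id, , drop = FALSE]
    familial <- shared_regions(fam_segments, fam_samples,
                               min_affected = min_affected,
                               genome = genome)
    paths$familial <- write_stage(familial, "familial_overlap")
    message(sprintf("[family-overlap] %d shared region(s)",
                    nrow(familial)))
  }

  annotations <- NULL
  if (annotate) {
    targets <- if (!is.null(assoc) && nrow(assoc$loci)) {
      assoc$loci[, c("chrom", "start", "end")]
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    if (!is.null(familial) && nrow(familial)) {
      targets <- rbind(targets, familial[, c("chrom", "start", "end")])
    }
    annotations <- annotate_regions(targets, genes)
    flat <- annotations
    flat$genes <- NULL
    paths$annotation <- write_stage(flat, "annotation")
    message(sprintf("[annotate] %d region(s) annotated", nrow(targets)))
  }

  invisible(list(qc = qc, burden = burden, association = assoc,
                 familial = familial, annotations = annotations,
                 paths = paths))
}
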