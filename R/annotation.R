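#' Read a gene list
#'
#' Accepts BED4 (`chrom, start, end, symbol`, 0-based half-open, no
#' header) or a headered TSV with columns `symbol, chrom, start, end`
#' (1-based inclusive, converted on read).
#'
#' @param path file path.
#' @param dialect `"bed"` (default) or `"tsv"`.
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_genes <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- read_tsv_checked(path, c("chrom", "start", "end", "symbol"),
                           header = FALSE)
  } else {
    df <- read_tsv_checked(path, c("symbol", "chrom", "start", "end"),
                           header = TRUE)
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (dialect == "tsv") df$start <- df$start - 1
  validate_genes(df[, c("symbol", "chrom", "start", "end")])
}

validate_genes <- function(genes) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) > 0) {
    if (any(genes$end <= genes$start)) stop("gene end must exceed start")
    if (any(is.na(genes$symbol) | genes$symbol == "")) {
      stop("gene symbols must be non-empty")
    }
  }
  genes
}

check_chrom_compat <- function(chrom_a, chrom_b) {
  if (length(chrom_a) == 0 || length(chrom_b) == 0) return(invisible())
  a <- unique(chrom_a); b <- unique(chrom_b)
  if (length(intersect(a, b)) == 0) {
    has_prefix <- function(x) any(grepl("^chr", x))
    if (has_prefix(a) != has_prefix(b)) {
      stop("chromosome naming mismatch between regions and genes ",
           "(e.g. 'chr1' vs '1'); normalize names before annotating")
    }
  }
  invisible()
}

#' Annotate regions with overlapping genes
#'
#' For each query region, lists the genes of `genes` that intersect it.
#' `mode = "any_overlap"` requires at least 1 bp of intersection;
#' `mode = "containment"` lists only genes whose interval lies entirely
#' within the region. Every listed gene carries its overlap width and a
#' containment flag, sorted by gene start within each region.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes data.frame as returned by [read_genes()].
#' @param mode `"any_overlap"` (default) or `"containment"`.
#' @return the input regions with a list-column `genes` (per-region
#'   data.frame of `symbol`, `overlap_bp`, `contained`) and a
#'   `gene_symbols` comma-joined summary column.
#' @export
annotate_regions <- function(regions, genes,
                             mode = c("any_overlap", "containment")) {
  mode <- match.arg(mode)
  check_chrom_compat(regions$chrom, genes$chrom)
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_regions, gr_genes)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_regions[q], gr_genes[s])
  widths <- GenomicRanges::width(ov)
  contained <- genes$start[s] >= regions$start[q] &
    genes$end[s] <= regions$end[q]
  if (mode == "containment") {
    keep <- contained
    q <- q[keep]; s <- s[keep]
    widths <- widths[keep]; contained <- contained[keep]
  }
  ann <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- which(q == i)
    sel <- sel[order(genes$start[s[sel]])]
    data.frame(symbol = genes$symbol[s[sel]],
               overlap_bp = widths[sel],
               contained = contained[sel])
  })
  out <- regions
  out$genes <- ann
  out$gene_symbols <- vapply(ann, function(g) {
    paste(g$symbol, collapse = ",")
  }, character(1))
  out
}

#' Summarize gene matches across annotated regions
#'
#' @param annotations result of [annotate_regions()].
#' @return list with `n_regions_with_genes` (regions overlapping at least
#'   one gene) and `n_distinct_genes` (unique symbols across all regions).
#' @export
summarize_matches <- function(annotations) {
  gene_lists <- annotations$genes
  n_hit <- sum(vapply(gene_lists, nrow, integer(1)) > 0)
  syms <- unique(unlist(lapply(gene_lists, `[[`, "symbol")))
  list(n_regions_with_genes = n_hit,
       n_distinct_genes = length(syms))
}
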