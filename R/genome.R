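#' Genome model: chromosome lengths and pseudo-autosomal regions
#'
#' A genome model records the chromosomes segments may live on (with their
#' lengths in bp) and the pseudo-autosomal regions (PARs) of the X
#' chromosome. PAR intervals are diploid in both sexes, so male X segments
#' touching a PAR are excluded from hemizygous-X logic rather than scored
#' against a ploidy of one.
#'
#' Intervals are stored 0-based half-open, the package-wide internal
#' convention.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, positive).
#' @param par_intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) giving PAR intervals; may have zero rows.
#' @param x_chrom name of the X chromosome in this model.
#' @param y_chrom name of the Y chromosome, or `NA` if absent.
#' @return an object of class `genome_model`.
#' @examples
#' gm <- genome_model(
#'   chromosomes = data.frame(chrom = c("chr1", "chrX"),
#'                            length = c(1e6, 5e5)),
#'   par_intervals = data.frame(chrom = "chrX", start = 0, end = 1e4)
#' )
#' @export
genome_model <- function(chromosomes, par_intervals = NULL,
                         x_chrom = "chrX", y_chrom = "chrY") {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicated chromosome names in genome model")
  }
  if (is.null(par_intervals) || nrow(par_intervals) == 0) {
    par_intervals <- data.frame(chrom = character(), start = numeric(),
                                end = numeric())
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(par_intervals)))
    par_intervals$chrom <- as.character(par_intervals$chrom)
    if (any(par_intervals$end <= par_intervals$start)) {
      stop("PAR intervals must have end > start")
    }
    xlen <- chromosomes$length[match(par_intervals$chrom, chromosomes$chrom)]
    if (anyNA(xlen) || any(par_intervals$end > xlen)) {
      stop("PAR intervals must lie within their chromosome bounds")
    }
  }
  structure(
    list(chromosomes = chromosomes, par_intervals = par_intervals,
         x_chrom = x_chrom, y_chrom = y_chrom),
    class = "genome_model"
  )
}

#' Default human genome model (hg19)
#'
#' Chromosome lengths for chr1-chr22, chrX and chrY (GRCh37/hg19) and the
#' two X-chromosome pseudo-autosomal regions PAR1 and PAR2 (0-based
#' half-open X coordinates). PAR coordinates are a configurable modelling
#' choice: callers working on another build or convention should construct
#' their own [genome_model()].
#'
#' @return a `genome_model`.
#' @export
default_genome <- function() {
  lengths <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
  )
  genome_model(
    chromosomes = data.frame(chrom = names(lengths), length = unname(lengths)),
    par_intervals = data.frame(
      chrom = "chrX",
      start = c(60000, 154931043),
      end = c(2699520, 155260560)
    )
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$par_intervals), "PAR interval(s)\n")
  invisible(x)
}

is_autosome <- function(chrom, genome) {
  chrom != genome$x_chrom & (is.na(genome$y_chrom) | chrom != genome$y_chrom)
}

chrom_length <- function(chrom, genome) {
  len <- genome$chromosomes$length[match(chrom, genome$chromosomes$chrom)]
  if (anyNA(len)) {
    stop("chromosome(s) not in genome model: ",
         paste(unique(chrom[is.na(len)]), collapse = ", "))
  }
  len
}

# TRUE where [start, end) intersects any PAR interval on the same chromosome
intersects_par <- function(chrom, start, end, genome) {
  par <- genome$par_intervals
  if (nrow(par) == 0) return(rep(FALSE, length(chrom)))
  out <- logical(length(chrom))
  for (i in seq_len(nrow(par))) {
    out <- out | (chrom == par$chrom[i] & start < par$end[i] & end > par$start[i])
  }
  out
}

#' Read / write a genome model as YAML
#'
#' The on-disk layout is a mapping with keys `chromosomes` (name -> length),
#' `par_intervals` (list of `{chrom, start, end}`, 0-based half-open),
#' `x_chrom` and `y_chrom`.
#'
#' @param path file path.
#' @return `read_genome()` returns a `genome_model`; `write_genome()`
#'   returns `path` invisibly.
#' @export
read_genome <- function(path) {
  y <- yaml::read_yaml(path)
  chroms <- data.frame(chrom = names(y$chromosomes),
                       length = as.numeric(unlist(y$chromosomes)))
  par <- if (length(y$par_intervals)) {
    do.call(rbind, lapply(y$par_intervals, function(p) {
      data.frame(chrom = p$chrom, start = as.numeric(p$start),
                 end = as.numeric(p$end))
    }))
  } else NULL
  genome_model(chroms, par,
               x_chrom = if (is.null(y$x_chrom)) "chrX" else y$x_chrom,
               y_chrom = if (is.null(y$y_chrom)) NA_character_ else y$y_chrom)
}

#' @rdname read_genome
#' @param genome a `genome_model`.
#' @export
write_genome <- function(genome, path) {
  y <- list(
    chromosomes = as.list(stats::setNames(genome$chromosomes$length,
                                          genome$chromosomes$chrom)),
    par_intervals = lapply(seq_len(nrow(genome$par_intervals)), function(i) {
      as.list(genome$par_intervals[i, c("chrom", "start", "end")])
    }),
    x_chrom = genome$x_chrom,
    y_chrom = genome$y_chrom
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
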