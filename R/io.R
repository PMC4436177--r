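#' Construct and validate a CNV segment table
#'
#' Segments are plain data.frames with one row per called copy-number
#' segment in one sample. Internally all coordinates are 0-based half-open,
#' so `length = end - start` with no off-by-one; the canonical TSV format
#' (and every report intended to be read next to a publication table) uses
#' 1-based inclusive coordinates, and [read_segments()] / [write_segments()]
#' convert between the two.
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates; `end > start` required.
#' @param copy_number non-negative integer copy-number calls.
#' @param n_markers optional positive integer marker counts (`NA` allowed).
#' @return a data.frame of class `cnv_segments` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `copy_number`, `n_markers` and a derived
#'   `length` column.
#' @export
cnv_segments <- function(sample_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         copy_number = integer(), n_markers = NA_integer_) {
  n <- max(length(sample_id), length(chrom), length(start), length(end),
           length(copy_number))
  df <- data.frame(
    sample_id = rep(as.character(sample_id), length.out = n),
    chrom = rep(as.character(chrom), length.out = n),
    start = rep(as.numeric(start), length.out = n),
    end = rep(as.numeric(end), length.out = n),
    copy_number = rep(as.integer(copy_number), length.out = n),
    n_markers = rep(as.integer(n_markers), length.out = n),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
}

validate_segments <- function(df) {
  required <- c("sample_id", "chrom", "start", "end", "copy_number")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("segment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"n_markers" %in% names(df)) df$n_markers <- NA_integer_
  if (nrow(df) > 0) {
    bad <- which(!(df$end > df$start))
    if (length(bad)) {
      stop("segment end must exceed start (row ", bad[1], ")")
    }
    if (any(df$copy_number < 0, na.rm = TRUE)) {
      stop("copy_number must be non-negative")
    }
    if (any(!is.na(df$n_markers) & df$n_markers < 1)) {
      stop("n_markers must be positive where present")
    }
  }
  df$length <- df$end - df$start
  class(df) <- c("cnv_segments", "data.frame")
  df
}

#' Read CNV segments from disk
#'
#' Two dialects are supported. `canonical_tsv` is a tab-separated file with
#' header `sample_id, chrom, start, end, copy_number, n_markers` whose
#' coordinates are 1-based inclusive; on read they are shifted to the
#' internal 0-based half-open convention (`start - 1`, `end` unchanged).
#' `bed` is BED6+2: `chrom, start, end, name, score, strand, copy_number,
#' n_markers`, already 0-based half-open, with the sample id in the `name`
#' column. Input row order is preserved.
#'
#' @param path file path.
#' @param dialect `"canonical_tsv"` (default) or `"bed"`.
#' @return a `cnv_segments` data.frame.
#' @export
read_segments <- function(path, dialect = c("canonical_tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "canonical_tsv") {
    df <- read_tsv_checked(
      path,
      c("sample_id", "chrom", "start", "end", "copy_number", "n_markers"),
      header = TRUE
    )
  } else {
    df <- read_tsv_checked(
      path,
      c("chrom", "start", "end", "name", "score", "strand",
        "copy_number", "n_markers"),
      header = FALSE
    )
    df <- data.frame(sample_id = as.character(df$name), chrom = df$chrom,
                     start = df$start, end = df$end,
                     copy_number = df$copy_number, n_markers = df$n_markers,
                     stringsAsFactors = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]))) {
      stop("malformed ", col, " at data line ", which(is.na(v))[1],
           " of ", path)
    }
    df[[col]] <- v
  }
  df$copy_number <- as.integer(df$copy_number)
  df$n_markers <- suppressWarnings(as.integer(df$n_markers))
  if (dialect == "canonical_tsv") {
    df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  }
  validate_segments(df)
}

read_tsv_checked <- function(path, cols, header) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = header,
                      stringsAsFactors = FALSE, comment.char = "#",
                      quote = "", colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(NULL)
      }
      stop("parse error in ", path, ": ", conditionMessage(e))
    }
  )
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols))
    return(df)
  }
  if (header) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(path, " lacks column(s): ", paste(missing, collapse = ", "))
    }
    df <- df[, cols, drop = FALSE]
  } else {
    if (ncol(df) < length(cols)) {
      stop(path, ": expected at least ", length(cols), " columns, found ",
           ncol(df))
    }
    df <- df[, seq_along(cols), drop = FALSE]
    names(df) <- cols
  }
  df
}

#' Write CNV segments to disk
#'
#' Inverse of [read_segments()]: `canonical_tsv` emits 1-based inclusive
#' coordinates, `bed` emits 0-based half-open BED6+2. Output is bit-stable
#' for a fixed input ordering.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param path output file path.
#' @param dialect `"canonical_tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path,
                           dialect = c("canonical_tsv", "bed")) {
  dialect <- match.arg(dialect)
  segments <- validate_segments(as.data.frame(segments))
  if (dialect == "canonical_tsv") {
    out <- data.frame(
      sample_id = segments$sample_id, chrom = segments$chrom,
      start = format_bp(segments$start + 1), end = format_bp(segments$end),
      copy_number = segments$copy_number, n_markers = segments$n_markers
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
  } else {
    out <- data.frame(
      chrom = segments$chrom, start = format_bp(segments$start),
      end = format_bp(segments$end), name = segments$sample_id,
      score = 0L, strand = ".",
      copy_number = segments$copy_number, n_markers = segments$n_markers
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Construct, read and write sample sheets
#'
#' A sample sheet has one row per sample: `sample_id` (unique), `sex`
#' (`male`/`female`/`unknown`), `status` (`case`/`control` for case-control
#' cohorts, `affected`/`unaffected` for pedigree members) and `family_id`,
#' which must be present exactly for pedigree statuses.
#'
#' @param sample_id,sex,status,family_id column vectors.
#' @return a validated data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, sex, status, family_id = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   sex = as.character(sex), status = as.character(status),
                   family_id = as.character(family_id),
                   stringsAsFactors = FALSE)
  validate_samples(df)
}

validate_samples <- function(df) {
  required <- c("sample_id", "sex", "status")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"family_id" %in% names(df)) df$family_id <- NA_character_
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of male, female, unknown")
  }
  if (!all(df$status %in% c("case", "control", "affected", "unaffected"))) {
    stop("status must be one of case, control, affected, unaffected")
  }
  familial <- df$status %in% c("affected", "unaffected")
  if (any(familial & (is.na(df$family_id) | df$family_id == ""))) {
    stop("family_id required for affected/unaffected samples")
  }
  if (any(!familial & !is.na(df$family_id))) {
    stop("family_id only allowed for affected/unaffected samples")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param path file path of a tab-separated sample sheet with header.
#' @export
read_samples <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "sex", "status", "family_id"),
                         header = TRUE)
  df$family_id[df$family_id %in% c("", "NA")] <- NA_character_
  validate_samples(df)
}

#' @rdname sample_sheet
#' @param samples a sample sheet data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(
    samples[, c("sample_id", "sex", "status", "family_id")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}
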