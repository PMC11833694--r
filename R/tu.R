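#' Transcription units
#'
#' A transcription unit (TU) is one analyzed gene body: a strand-aware genomic
#' interval together with per-nucleotide adjusted read counts and a validity
#' mask. Coordinates are 0-based half-open ([start, end)), the convention of
#' BED/bedGraph. Counts and mask are stored 5'-to-3' in transcription order, so
#' for a minus-strand TU element 1 corresponds to genomic position `end - 1`.
#'
#' @param id character identifier.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open genomic interval of the (trimmed) gene
#'   body.
#' @param counts optional numeric vector of non-negative per-nucleotide read
#'   counts, length `end - start`, in transcription order. Defaults to zeros.
#' @param mask optional logical vector, `TRUE` at usable sites. Defaults to all
#'   `TRUE`.
#' @return An object of class `elr_tu`.
#' @examples
#' tu <- transcription_unit("g1", "chr1", "+", 0, 10, counts = rep(1, 10))
#' tu_length(tu)
#' @export
transcription_unit <- function(id, chrom, strand, start, end,
                               counts = NULL, mask = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(strand %in% c("+", "-"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("TU '", id, "': start must be < end")
  n <- as.integer(end - start)
  if (is.null(counts)) counts <- numeric(n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(counts) != n)
    stop("TU '", id, "': length(counts) must equal end - start")
  if (length(mask) != n)
    stop("TU '", id, "': length(mask) must equal end - start")
  if (any(counts < 0)) stop("TU '", id, "': negative counts")
  structure(
    list(id = id, chrom = chrom, strand = strand,
         start = start, end = end,
         counts = as.numeric(counts), mask = as.logical(mask)),
    class = "elr_tu")
}

#' @export
print.elr_tu <- function(x, ...) {
  cat(sprintf("<elr_tu> %s %s:%g-%g(%s), %d nt, %.3g reads, %d masked\n",
              x$id, x$chrom, x$start, x$end, x$strand, tu_length(x),
              sum(x$counts), sum(!x$mask)))
  invisible(x)
}

#' Number of nucleotides in a TU body
#' @param tu an `elr_tu`.
#' @export
tu_length <- function(tu) length(tu$counts)

#' Convert a genomic position to a 5'-to-3' index within a TU
#'
#' @param tu an `elr_tu`.
#' @param pos 0-based genomic position(s).
#' @return 1-based index into `tu$counts` (NA outside the body).
#' @export
tu_index <- function(tu, pos) {
  idx <- if (tu$strand == "+") pos - tu$start + 1 else tu$end - pos
  idx[pos < tu$start | pos >= tu$end] <- NA_integer_
  as.integer(idx)
}

#' Interval sets
#'
#' A light container for genomic intervals (0-based half-open), used for peak
#' annotations, feature coverage, masks and gene bodies.
#'
#' @param chrom,start,end vectors defining the intervals.
#' @param strand optional strand vector (`"+"`, `"-"` or `"."`).
#' @param score optional numeric score.
#' @return A data frame of class `elr_intervals`, sorted by (chrom, start).
#' @export
interval_set <- function(chrom, start, end, strand = NULL, score = NULL) {
  if (any(start >= end)) stop("interval_set: start must be < end")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df$strand <- if (is.null(strand)) "." else as.character(strand)
  if (!is.null(score)) df$score <- as.numeric(score)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("elr_intervals", "data.frame")
  df
}

#' Read a BED file into an interval set
#'
#' Supports BED3-BED6 (chrom, start, end, name, score, strand); extra columns
#' are ignored. Lines starting with `track`, `browser` or `#` are skipped.
#'
#' @param path file path.
#' @return An [interval_set()]; BED name column, when present, is kept as
#'   `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(interval_set(character(), numeric(), numeric() + 1))
  fields <- strsplit(lines, "\t| +")
  ncol <- min(lengths(fields))
  get <- function(k) vapply(fields, `[[`, "", k)
  iv <- interval_set(get(1), as.numeric(get(2)), as.numeric(get(3)),
                     strand = if (ncol >= 6) get(6) else NULL,
                     score = if (ncol >= 5) suppressWarnings(as.numeric(get(5))) else NULL)
  if (ncol >= 4) {
    nm <- get(4)
    o <- order(get(1), as.numeric(get(2)))
    iv$name <- nm[o]
  }
  iv
}

# Internal: rows of an interval set overlapping [start, end) on chrom
overlap_intervals <- function(iv, chrom, start, end) {
  iv[iv$chrom == chrom & iv$end > start & iv$start < end, , drop = FALSE]
}
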