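# bedGraph readers/writers. The dialect is deliberately minimal: four
# tab-separated columns, 0-based half-open intervals, no track lines required
# (track/browser/# lines are skipped on read). Positions absent from a file
# are zero. Minus-strand values are stored as negative numbers on disk, the
# usual convention for strand-resolved nascent-RNA tracks.

read_bedgraph_table <- function(path) {
  lines <- tryCatch(readLines(path), error = function(e) character())
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 4L))
    stop("read_bedgraph: malformed line (need 4 columns) in ", path)
  data.frame(chrom = vapply(fields, `[[`, "", 1),
             start = as.numeric(vapply(fields, `[[`, "", 2)),
             end = as.numeric(vapply(fields, `[[`, "", 3)),
             value = as.numeric(vapply(fields, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Read a per-nucleotide count (or covariate) track for a set of TUs
#'
#' Reads a bedGraph file and expands it to per-nucleotide values over each TU
#' body, oriented 5'-to-3' along transcription (values over a minus-strand TU
#' are flipped). Positions absent from the file are 0.
#'
#' Negative values are accepted only over minus-strand TUs, where they are
#' interpreted as the usual signed convention for minus-strand signal and
#' their absolute value is used; a negative value overlapping a plus-strand TU
#' is an error.
#'
#' @param path bedGraph file path.
#' @param tus a list of [transcription_unit()] objects.
#' @param chrom_sizes optional named vector of contig lengths; when given,
#'   intervals on unknown contigs or exceeding contig bounds raise an error
#'   naming the contig.
#' @param raw if `TRUE`, values are returned exactly as stored (no sign
#'   policy) -- for covariate tracks, which are legitimately signed. The
#'   default applies the count-track convention above.
#' @return A named list of numeric vectors, one per TU, in transcription order.
#' @export
read_counts_track <- function(path, tus, chrom_sizes = NULL, raw = FALSE) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  bg <- read_bedgraph_table(path)
  if (!is.null(chrom_sizes)) {
    bad <- !(bg$chrom %in% names(chrom_sizes))
    if (any(bad))
      stop("read_counts_track: unknown contig '", bg$chrom[bad][1], "' in ", path)
    over <- bg$end > chrom_sizes[bg$chrom]
    if (any(over))
      stop("read_counts_track: interval exceeds bounds of contig '",
           bg$chrom[over][1], "'")
  }
  out <- lapply(tus, function(tu) {
    v <- numeric(tu_length(tu))
    sel <- bg[bg$chrom == tu$chrom & bg$end > tu$start & bg$start < tu$end, ,
              drop = FALSE]
    if (nrow(sel)) {
      if (!raw && any(sel$value < 0) && tu$strand == "+")
        stop("read_counts_track: negative value over plus-strand TU '",
             tu$id, "'")
      for (k in seq_len(nrow(sel))) {
        lo <- max(sel$start[k], tu$start)
        hi <- min(sel$end[k], tu$end)
        v[(lo - tu$start + 1):(hi - tu$start)] <-
          if (raw) sel$value[k] else abs(sel$value[k])
      }
      if (tu$strand == "-") v <- rev(v)
    }
    v
  })
  names(out) <- vapply(tus, `[[`, "", "id")
  out
}

#' Write per-nucleotide values as a bedGraph track
#'
#' Runs of equal value are merged into single intervals. Values over
#' minus-strand TUs are written as negative numbers (positive values represent
#' plus-strand signal, negative values minus-strand signal). Zero runs are
#' omitted, matching the sparse bedGraph convention used by
#' [read_counts_track()], so write/read round-trips are lossless.
#'
#' @param values numeric vector (single TU) or list of vectors, 5'-to-3' in
#'   transcription order, one value per nucleotide.
#' @param tus matching [transcription_unit()] or list thereof.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, tus, path) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  if (!is.list(values)) values <- list(values)
  stopifnot(length(values) == length(tus))
  for (s in c("+", "-")) {
    sel <- vapply(tus, function(t) t$strand == s, TRUE)
    st <- tus[sel]
    if (length(st) > 1L) {
      key <- order(vapply(st, `[[`, "", "chrom"),
                   vapply(st, `[[`, 0, "start"))
      st <- st[key]
      for (k in seq_len(length(st) - 1L)) {
        if (st[[k]]$chrom == st[[k + 1L]]$chrom &&
            st[[k]]$end > st[[k + 1L]]$start)
          stop("write_bedgraph: overlapping TUs on strand ", s, ": '",
               st[[k]]$id, "' and '", st[[k + 1L]]$id, "'")
      }
    }
  }
  rows <- list()
  for (k in seq_along(tus)) {
    tu <- tus[[k]]
    v <- values[[k]]
    if (length(v) != tu_length(tu))
      stop("write_bedgraph: values/TU length mismatch for '", tu$id, "'")
    if (tu$strand == "-") v <- -rev(v)  # genomic order, signed
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tu$chrom, start = tu$start + starts[keep],
        end = tu$start + ends[keep], value = r$values[keep],
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
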