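#' Read a genome FASTA file
#'
#' Sequences are case-folded to uppercase and any character outside A/C/G/T is
#' replaced by N, so downstream k-mer indicators have well-defined semantics.
#'
#' @param path path to a (plain, uncompressed or gzip) FASTA file.
#' @return A named character vector of class `elr_genome`, one element per
#'   contig.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("read_fasta: duplicate FASTA headers: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- nm
  structure(seqs, class = "elr_genome")
}

#' @export
print.elr_genome <- function(x, ...) {
  cat("<elr_genome>", length(x), "contig(s):",
      paste(sprintf("%s (%d nt)", names(x), nchar(unclass(x))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reverse-complement a nucleotide string
#'
#' N is its own complement. `revcomp(revcomp(x)) == x`.
#'
#' @param seq character string over A/C/G/T/N.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Transcription-strand sequence of a TU
#'
#' Extracts the genome sequence of the TU body, reverse-complemented for
#' minus-strand TUs, so base 1 of the result is the 5'-most transcribed base.
#'
#' @param genome an [read_fasta()] genome (or named character vector).
#' @param tu an `elr_tu`.
#' @return A character string of length `tu_length(tu)`.
#' @export
tu_sequence <- function(genome, tu) {
  if (!tu$chrom %in% names(genome))
    stop("tu_sequence: contig '", tu$chrom, "' not found in genome")
  contig <- unclass(genome)[[tu$chrom]]
  if (tu$end > nchar(contig))
    stop("tu_sequence: TU '", tu$id, "' exceeds contig '", tu$chrom, "' bounds")
  s <- substr(contig, tu$start + 1, tu$end)
  if (tu$strand == "-") s <- revcomp(s)
  s
}
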