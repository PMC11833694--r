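#' Dense per-nucleotide covariate matrices
#'
#' Container for the covariate vectors \eqn{Y_{i,j}} entering the elongation
#' GLM: one numeric matrix per TU (sites x features), optionally with a
#' defined-mask per feature (e.g. DNA methylation is defined at CpG sites
#' only). Standardization statistics are attached by [standardize()].
#'
#' @param values a matrix (single TU) or list of matrices, sites x features,
#'   all with the same number of columns.
#' @param names feature names; defaults to the first matrix's colnames.
#' @param defined optional logical matrix/list of matrices of the same shapes:
#'   `TRUE` where the raw feature is defined. `NULL` means defined everywhere.
#' @return An object of class `elr_features`.
#' @export
feature_matrix <- function(values, names = NULL, defined = NULL) {
  if (is.matrix(values)) values <- list(values)
  values <- lapply(values, function(v) {
    if (!is.matrix(v)) v <- matrix(v, ncol = 1L)
    storage.mode(v) <- "double"
    v
  })
  nf <- unique(vapply(values, ncol, 0L))
  if (length(nf) != 1L)
    stop("feature_matrix: all TUs must have the same number of features")
  if (is.null(names)) names <- colnames(values[[1]])
  if (is.null(names)) names <- paste0("f", seq_len(nf))
  if (length(names) != nf) stop("feature_matrix: bad feature names length")
  values <- lapply(values, function(v) { colnames(v) <- names; v })
  if (!is.null(defined)) {
    if (is.matrix(defined)) defined <- list(defined)
    stopifnot(length(defined) == length(values))
    for (k in seq_along(defined))
      stopifnot(identical(dim(defined[[k]]), dim(values[[k]])))
  }
  structure(list(values = values, names = names, defined = defined,
                 center = NULL, scale = NULL, standardized = FALSE),
            class = "elr_features")
}

#' @export
print.elr_features <- function(x, ...) {
  cat(sprintf("<elr_features> %d TU(s), %d feature(s)%s: %s\n",
              length(x$values), length(x$names),
              if (x$standardized) " (standardized)" else "",
              paste(head(x$names, 8), collapse = ", ")))
  invisible(x)
}

n_features <- function(fm) length(fm$names)

#' Standardize covariates to mean 0, sd 1
#'
#' Per feature, statistics are computed over defined sites only (population
#' standard deviation, i.e. dividing by n); defined sites become
#' `(y - mean)/sd` and undefined sites are set to exactly 0 so they contribute
#' neither positively nor negatively to the linear predictor. Constant
#' features (sd 0) are dropped with a warning. The statistics are stored on
#' the result so that sufficient statistics can later be computed from the
#' raw sparse values by a linear transformation, and so that held-out data can
#' be standardized with training statistics (see `stats_from`).
#'
#' @param fm an [feature_matrix()] or [kmer_features()] object.
#' @param stats_from optional integer vector of TU indices over which to
#'   compute the statistics (e.g. training TUs); values of all TUs are
#'   transformed. Default: all TUs.
#' @param ... unused.
#' @return An object of the same class with `standardized = TRUE` and
#'   `center`/`scale` filled in.
#' @export
standardize <- function(fm, ...) UseMethod("standardize")

#' @rdname standardize
#' @export
standardize.elr_features <- function(fm, stats_from = NULL, ...) {
  idx <- if (is.null(stats_from)) seq_along(fm$values) else stats_from
  nf <- n_features(fm)
  ctr <- scl <- numeric(nf)
  for (n in seq_len(nf)) {
    vals <- unlist(lapply(idx, function(k) {
      v <- fm$values[[k]][, n]
      if (!is.null(fm$defined)) v[fm$defined[[k]][, n]] else v
    }), use.names = FALSE)
    if (length(vals) == 0L) { scl[n] <- 0; next }
    ctr[n] <- mean(vals)
    scl[n] <- sqrt(mean((vals - ctr[n])^2))
  }
  keep <- scl > 0
  if (!all(keep))
    warning("standardize: dropping constant feature(s): ",
            paste(fm$names[!keep], collapse = ", "))
  values <- lapply(seq_along(fm$values), function(k) {
    v <- fm$values[[k]][, keep, drop = FALSE]
    out <- sweep(sweep(v, 2, ctr[keep]), 2, scl[keep], "/")
    if (!is.null(fm$defined)) {
      d <- fm$defined[[k]][, keep, drop = FALSE]
      out[!d] <- 0
    }
    out
  })
  res <- feature_matrix(values, names = fm$names[keep],
                        defined = if (is.null(fm$defined)) NULL else
                          lapply(fm$defined, function(d) d[, keep, drop = FALSE]))
  res$center <- ctr[keep]; res$scale <- scl[keep]
  names(res$center) <- names(res$scale) <- res$names
  res$standardized <- TRUE
  res
}

# Apply existing standardization statistics to raw features
apply_standardization <- function(fm, center, scale) {
  stopifnot(inherits(fm, "elr_features"))
  keep <- match(names(center), fm$names)
  if (anyNA(keep)) stop("apply_standardization: missing features")
  values <- lapply(seq_along(fm$values), function(k) {
    v <- fm$values[[k]][, keep, drop = FALSE]
    out <- sweep(sweep(v, 2, center), 2, scale, "/")
    if (!is.null(fm$defined)) out[!fm$defined[[k]][, keep, drop = FALSE]] <- 0
    out
  })
  res <- feature_matrix(values, names = fm$names[keep])
  res$center <- center; res$scale <- scale; res$standardized <- TRUE
  res
}

#' DNA k-mer indicator features
#'
#' Builds indicator columns marking sites whose surrounding sequence matches
#' each k-mer, aligned to the Pol II active site: for odd k the middle base of
#' the k-mer is aligned with the site; for even k the base at (1-based)
#' position k/2 is aligned, so the active site falls just left of center. A
#' signed `shift` moves the alignment point: the indicator at site i under
#' shift s equals the unshifted indicator at site i + s (negative = the k-mer
#' lies upstream of the active site). Windows overrunning the TU ends or
#' containing N are 0.
#'
#' @param seq transcription-strand sequence of the TU (character string).
#' @param kmers character vector of k-mers over A/C/G/T (k >= 1).
#' @param shift integer alignment shift in nucleotides.
#' @return Integer matrix, `nchar(seq)` rows x `length(kmers)` columns.
#' @examples
#' kmer_indicators("GCAT", "CA")   # active site on the C
#' @export
kmer_indicators <- function(seq, kmers, shift = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (any(grepl("[^ACGT]", kmers)))
    stop("kmer_indicators: k-mers must be over A/C/G/T")
  n <- nchar(seq)
  out <- matrix(0L, n, length(kmers), dimnames = list(NULL, kmers))
  for (m in seq_along(kmers)) {
    km <- kmers[m]
    k <- nchar(km)
    p <- if (k %% 2L == 1L) (k + 1L) %/% 2L else k %/% 2L
    # site i matches iff seq[i + shift - p + 1 .. i + shift - p + k] == km
    starts <- seq_len(n) + shift - p
    ok <- starts >= 0L & starts + k <= n
    if (!any(ok)) next
    win <- substring(seq, starts[ok] + 1L, starts[ok] + k)
    out[which(ok)[win == km], m] <- 1L
  }
  out
}
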