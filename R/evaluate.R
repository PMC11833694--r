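# Model evaluation and downstream summaries.

#' Windowed prediction r-squared
#'
#' Per-nucleotide read counts are too sparse to predict individually, so
#' predictive performance is scored on window averages: for each window
#' size, both tracks are averaged within non-overlapping windows (tiled from
#' the 5' end, partial windows dropped), windows are pooled across TUs, and
#' the squared Pearson correlation is reported. Invariant to affine
#' rescaling of either track.
#'
#' @param predicted,observed lists of per-nucleotide tracks, parallel.
#' @param window_sizes integer vector of window sizes in nucleotides.
#' @return Named numeric vector of r^2, one per window size.
#' @export
windowed_r2 <- function(predicted, observed, window_sizes) {
  if (!is.list(predicted)) predicted <- list(predicted)
  if (!is.list(observed)) observed <- list(observed)
  stopifnot(length(predicted) == length(observed))
  lens <- lengths(observed)
  out <- stats::setNames(numeric(length(window_sizes)),
                         as.character(window_sizes))
  for (k in seq_along(window_sizes)) {
    w <- window_sizes[k]
    if (all(lens < w))
      stop("windowed_r2: window size ", w, " larger than every TU")
    pw <- ow <- numeric()
    for (j in seq_along(predicted)) {
      nwin <- floor(lens[j] / w)
      if (nwin < 1) next
      idx <- rep(seq_len(nwin), each = w)
      pw <- c(pw, as.numeric(tapply(predicted[[j]][seq_along(idx)], idx, mean)))
      ow <- c(ow, as.numeric(tapply(observed[[j]][seq_along(idx)], idx, mean)))
    }
    out[k] <- if (var(pw) == 0 || var(ow) == 0) 0 else stats::cor(pw, ow)^2
  }
  out
}

#' Cluster 5-mer coefficients and build enrichment matrices
#'
#' Fitted 5-mers are split by coefficient sign; within each sign group the
#' top candidates by |kappa| (at most `top_n`) are clustered on their scalar
#' kappa values with K-means (Hartigan-Wong, fixed seed, 10 restarts), and
#' each cluster is summarized by a position-frequency matrix (positions x
#' A/C/G/T, rows summing to 1, unweighted base frequencies across member
#' 5-mers) suitable for sequence-logo rendering. Degenerate groups (fewer
#' than 2 distinct values) collapse to a single cluster with a warning.
#'
#' @param kappa named coefficient vector over k-mers of a common length.
#' @param top_n candidates per sign group.
#' @param K number of clusters per group.
#' @param seed seed for the K-means restarts.
#' @param zero_threshold coefficients below this magnitude are ignored.
#' @return A list with elements `positive` and `negative`, each a list of
#'   `kmers`, `kappa`, `cluster` (assignments) and `pfm` (list of matrices,
#'   one per cluster).
#' @export
cluster_kmers <- function(kappa, top_n = 50, K = 2, seed = 1,
                          zero_threshold = 1e-6) {
  stopifnot(!is.null(names(kappa)))
  klen <- unique(nchar(names(kappa)))
  stopifnot(length(klen) == 1L)
  set.seed(seed)
  one_group <- function(kap) {
    if (length(kap) == 0)
      return(list(kmers = character(), kappa = numeric(),
                  cluster = integer(), pfm = list()))
    kap <- kap[order(-abs(kap))]
    kap <- head(kap, top_n)
    if (length(kap) < 2 || length(unique(kap)) < K) {
      if (length(kap) >= 2)
        warning("cluster_kmers: degenerate group, returning one cluster")
      cl <- rep(1L, length(kap))
    } else {
      cl <- kmeans(matrix(kap, ncol = 1), centers = K, nstart = 10)$cluster
    }
    pfm <- lapply(sort(unique(cl)), function(g) {
      members <- names(kap)[cl == g]
      m <- sapply(c("A", "C", "G", "T"), function(b)
        vapply(seq_len(klen), function(p)
          mean(substr(members, p, p) == b), 0))
      m <- matrix(m, nrow = klen,
                  dimnames = list(paste0("pos", seq_len(klen)),
                                  c("A", "C", "G", "T")))
      m
    })
    list(kmers = names(kap), kappa = kap, cluster = cl, pfm = pfm)
  }
  list(positive = one_group(kappa[kappa > zero_threshold]),
       negative = one_group(kappa[kappa < -zero_threshold]))
}

#' Export predicted elongation-rate tracks as bedGraph
#'
#' Writes \eqn{\hat\zeta} for the given TUs to a bedGraph file, using the
#' signed strand convention: positive values are plus-strand rates,
#' negative values minus-strand rates.
#'
#' @param fit an `elr_glm_fit`.
#' @param tus TUs to export.
#' @param features matching covariates.
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
export_rate_track <- function(fit, tus, features, path) {
  zeta <- predict_zeta(fit, features)
  write_bedgraph(zeta, tus, path)
}
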