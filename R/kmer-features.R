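# Grouped k-mer feature representation.
#
# All k-mer indicators with k <= 5 (aligned to the active site, see
# kmer_indicators) are functions of the 5-base sequence window centered on the
# site, with positions beyond the TU treated as N. Sites are therefore grouped
# by their window (at most 5^5 distinct windows), and all sufficient
# statistics of the GLM reduce to per-gene counts over groups. Combined with
# the linear-transformation trick for standardization -- kappa . Y_std =
# (kappa/s) . Y_raw - sum(kappa * m / s) -- this makes each gradient-ascent
# iteration cost O(genes x groups) instead of O(genes x sites x features).

BASE5 <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(b), k), stringsAsFactors = FALSE)))
}

# window code per site: sum over t=0..4 of digit(i-2+t) * 5^t, N-padded
window_codes <- function(seq) {
  n <- nchar(seq)
  lut <- integer(256); lut[] <- 4L
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("T") + 1L] <- 3L
  d <- c(4L, 4L, lut[utf8ToInt(seq) + 1L], 4L, 4L)
  code <- integer(n)
  for (t in 0:4) code <- code + d[seq_len(n) + t] * 5L^t
  code
}

decode_window <- function(code) {
  b <- c("A", "C", "G", "T", "N")
  chars <- matrix("", length(code), 5L)
  for (t in 0:4) {
    chars[, t + 1L] <- b[(code %% 5L) + 1L]
    code <- code %/% 5L
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Grouped k-mer indicator features for a set of TUs
#'
#' Efficient representation of k-mer indicator covariates (k <= 5) for the
#' elongation GLM: sites are grouped by the 5-base window around the active
#' site, and the (sparse) matrix of raw indicator values is stored once per
#' distinct window. This is exactly equivalent to the dense indicators of
#' [kmer_indicators()] (see [as_dense_features()]), but lets the fitter work
#' from per-gene window counts.
#'
#' @param seqs list of transcription-strand TU sequences (see
#'   [tu_sequence()]).
#' @param kmers either a character vector of k-mers, a single integer k (all
#'   4^k k-mers), or `"k<=5"` for all 1364 k-mers of sizes 1-5.
#' @param shift signed alignment shift in nucleotides, as in
#'   [kmer_indicators()]; must satisfy |shift| <= 25.
#' @return An object of class `elr_kmer_features`.
#' @export
kmer_features <- function(seqs, kmers = 5L, shift = 0L) {
  if (is.character(seqs)) seqs <- as.list(seqs)
  if (identical(kmers, "k<=5")) kmers <- unlist(lapply(1:5, all_kmers))
  else if (is.numeric(kmers)) {
    stopifnot(length(kmers) == 1L, kmers >= 1L, kmers <= 5L)
    kmers <- all_kmers(as.integer(kmers))
  }
  if (any(grepl("[^ACGT]", kmers)) || any(nchar(kmers) > 5L))
    stop("kmer_features: k-mers must be over A/C/G/T with k <= 5")
  if (abs(shift) > 25L) stop("kmer_features: |shift| must be <= 25")

  gid <- vector("list", length(seqs))
  codes_seen <- integer()
  raw <- lapply(seqs, window_codes)
  for (j in seq_along(seqs)) {
    cj <- raw[[j]]
    if (shift != 0L) {
      n <- length(cj)
      # shifted window: sites looking past the TU end see an all-N window
      allN <- sum(4L * 5L^(0:4))
      idx <- seq_len(n) + shift
      cj <- ifelse(idx >= 1L & idx <= n, cj[pmin(pmax(idx, 1L), n)], allN)
    }
    raw[[j]] <- cj
  }
  codes <- sort(unique(unlist(raw, use.names = FALSE)))
  for (j in seq_along(raw)) gid[[j]] <- match(raw[[j]], codes)

  win <- decode_window(codes)
  ii <- integer(); jj <- integer()
  for (m in seq_along(kmers)) {
    k <- nchar(kmers[m])
    p <- if (k %% 2L == 1L) (k + 1L) %/% 2L else k %/% 2L
    a <- 4L - p  # 1-based start of the k-mer inside the window
    hit <- substr(win, a, a + k - 1L) == kmers[m]
    if (any(hit)) {
      ii <- c(ii, which(hit))
      jj <- c(jj, rep.int(m, sum(hit)))
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(codes), length(kmers)),
                            dimnames = list(NULL, kmers))
  central <- (codes %/% 25L) %% 5L  # digit at offset 0: 0=A,1=C,2=G,3=T,4=N
  structure(list(gid = gid, codes = codes, P = P, names = kmers,
                 central_base = central, shift = as.integer(shift),
                 center = NULL, scale = NULL, standardized = FALSE),
            class = "elr_kmer_features")
}

#' @export
print.elr_kmer_features <- function(x, ...) {
  cat(sprintf("<elr_kmer_features> %d TU(s), %d k-mer(s), %d window group(s)%s\n",
              length(x$gid), length(x$names), length(x$codes),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

# Per-group site counts (or weighted counts), per TU. `masks` and `weights`
# are lists parallel to `tu_idx`; masked-out sites are excluded entirely.
kmer_group_counts <- function(kf, tu_idx = NULL, masks = NULL,
                              weights = NULL) {
  idx <- if (is.null(tu_idx)) seq_along(kf$gid) else tu_idx
  G <- length(kf$codes)
  out <- matrix(0, G, length(idx))
  for (m in seq_along(idx)) {
    g <- kf$gid[[idx[m]]]
    if (!is.null(masks)) g <- g[masks[[m]]]
    if (is.null(weights)) {
      out[, m] <- tabulate(g, nbins = G)
    } else {
      w <- weights[[m]]
      if (!is.null(masks)) w <- w[masks[[m]]]
      s <- rowsum(w, g)
      out[as.integer(rownames(s)), m] <- s[, 1]
    }
  }
  out
}

#' @rdname standardize
#' @export
standardize.elr_kmer_features <- function(fm, stats_from = NULL, ...) {
  idx <- if (is.null(stats_from)) seq_along(fm$gid) else stats_from
  G <- length(fm$codes)
  ntot <- numeric(G)
  for (j in idx) ntot <- ntot + tabulate(fm$gid[[j]], nbins = G)
  N <- sum(ntot)
  m <- as.numeric(Matrix::crossprod(fm$P, ntot)) / N
  ex2 <- as.numeric(Matrix::crossprod(fm$P^2, ntot)) / N
  v <- pmax(ex2 - m^2, 0)
  keep <- v > 0
  if (!all(keep))
    warning("standardize: dropping constant k-mer feature(s): ",
            paste(head(fm$names[!keep], 10), collapse = ", "),
            if (sum(!keep) > 10) " ..." else "")
  out <- fm
  out$P <- fm$P[, keep, drop = FALSE]
  out$names <- fm$names[keep]
  out$center <- stats::setNames(m[keep], out$names)
  out$scale <- stats::setNames(sqrt(v[keep]), out$names)
  out$standardized <- TRUE
  out
}

#' Expand grouped k-mer features to dense matrices
#'
#' Mainly for verification and small examples: returns the dense per-TU
#' covariate matrices equivalent to the grouped representation (standardized
#' values if statistics are attached, raw 0/1 indicators otherwise).
#'
#' @param kf an [kmer_features()] object.
#' @return An [feature_matrix()].
#' @export
as_dense_features <- function(kf) {
  stopifnot(inherits(kf, "elr_kmer_features"))
  Pd <- as.matrix(kf$P)
  values <- lapply(kf$gid, function(g) {
    Y <- Pd[g, , drop = FALSE]
    rownames(Y) <- NULL
    Y
  })
  fm <- feature_matrix(values, names = kf$names)
  if (kf$standardized) {
    fm$values <- lapply(fm$values, function(Y)
      sweep(sweep(Y, 2, kf$center), 2, kf$scale, "/"))
    fm$center <- kf$center; fm$scale <- kf$scale; fm$standardized <- TRUE
  }
  fm
}
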