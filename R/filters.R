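#' Smoothing filters for genomic features
#'
#' A smoothing filter spreads the influence of a narrowly annotated feature
#' (a splice site, a CTCF motif hit) over adjacent nucleotides before the
#' feature enters the regression, or puts datasets of different genomic
#' resolution on a common scale. A filter is defined by a radius `r`, a
#' bandwidth `sigma` (Gaussian only), an integer offset `delta`, and for the
#' generalized form a vector of 2r+1 non-negative weights. The filtered value
#' at site i is
#' \deqn{\bar Y_i = \frac{1}{Z}\sum_{k=-r}^{r} Y_{i+k+\delta} F(k), \qquad
#'       Z = \sum_{k=-r}^{r} F(k),}
#' with the Gaussian kernel \eqn{F(k) = \sigma^{-1}\exp(-(k/\sigma)^2/2)} and
#' the generalized kernel \eqn{F(k) = \lambda_{k+r}}. Values outside the track
#' are treated as 0 (zero padding).
#'
#' The package defaults mirror the settings used for the epigenomic model:
#' ChIP-seq-based features (histone marks, CTCF) use a Gaussian filter with
#' r = 400 nt, sigma = 100 nt; RNA stem-loops use r = 500 nt, sigma = 200 nt;
#' splice sites use generalized filters estimated from metaplots via
#' [estimate_generalized_filter()].
#'
#' @param r radius in nucleotides (> 0).
#' @param sigma Gaussian bandwidth in nucleotides (> 0).
#' @param delta integer offset in nucleotides (0 = centered on the site).
#' @param weights numeric vector of length 2r+1 of non-negative scale factors.
#' @return An object of class `elr_filter`.
#' @examples
#' f <- gaussian_filter(r = 2, sigma = 1)
#' apply_filter(c(0, 0, 1, 0, 0), f)
#' @export
gaussian_filter <- function(r, sigma, delta = 0L) {
  stopifnot(r > 0, sigma > 0)
  structure(list(kind = "gaussian", r = as.integer(r), sigma = sigma,
                 delta = as.integer(delta), weights = NULL),
            class = "elr_filter")
}

#' @rdname gaussian_filter
#' @export
generalized_filter <- function(weights, delta = 0L) {
  weights <- as.numeric(weights)
  if (length(weights) %% 2L != 1L)
    stop("generalized_filter: weights must have odd length 2r+1")
  if (any(weights < 0)) stop("generalized_filter: negative weights")
  if (all(weights == 0)) stop("generalized_filter: all-zero weights")
  r <- (length(weights) - 1L) %/% 2L
  if (r < 1L) stop("generalized_filter: radius must be > 0")
  structure(list(kind = "generalized", r = r, sigma = NULL,
                 delta = as.integer(delta), weights = weights),
            class = "elr_filter")
}

#' @export
print.elr_filter <- function(x, ...) {
  cat(sprintf("<elr_filter> %s, r=%d, delta=%d%s\n", x$kind, x$r, x$delta,
              if (x$kind == "gaussian") sprintf(", sigma=%g", x$sigma) else ""))
  invisible(x)
}

# Kernel values F(k), k = -r..r (unnormalized)
filter_kernel <- function(spec) {
  k <- seq(-spec$r, spec$r)
  if (spec$kind == "gaussian") exp(-0.5 * (k / spec$sigma)^2) / spec$sigma
  else spec$weights
}

#' Apply a smoothing filter to a per-nucleotide track
#'
#' @param x numeric vector of raw per-nucleotide values.
#' @param spec an `elr_filter` from [gaussian_filter()] or
#'   [generalized_filter()].
#' @return Numeric vector of the same length; out-of-range raw values are
#'   treated as 0.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "elr_filter"))
  w <- filter_kernel(spec)
  Z <- sum(w)
  if (Z <= 0) stop("apply_filter: filter normalizer is not positive")
  n <- length(x)
  pad <- spec$r + abs(spec$delta)
  xp <- c(numeric(pad), x, numeric(pad))
  y <- numeric(n)
  ks <- seq(-spec$r, spec$r)
  for (m in seq_along(ks)) {
    if (w[m] == 0) next
    off <- ks[m] + spec$delta
    y <- y + w[m] * xp[pad + seq_len(n) + off]
  }
  y / Z
}

#' Estimate a generalized filter from a metaplot profile
#'
#' Generalized filter weights are derived from the average relative read-depth
#' profile around instances of the feature (see [metaplot()]): the profile
#' median is taken as the baseline and the positive excursion above it becomes
#' the kernel, so the filter spreads the feature's influence with the same
#' shape the data show around it.
#'
#' @param profile numeric profile over offsets -r..r (length exactly 2r+1; a
#'   longer profile is an error, use the matching radius).
#' @param r radius in nucleotides.
#' @param delta offset, passed through to the filter.
#' @return A [generalized_filter()].
#' @export
estimate_generalized_filter <- function(profile, r, delta = 0L) {
  if (length(profile) < 2L * r + 1L)
    stop("estimate_generalized_filter: profile shorter than 2r+1")
  if (length(profile) != 2L * r + 1L)
    stop("estimate_generalized_filter: profile length must be exactly 2r+1")
  w <- pmax(profile - median(profile), 0)
  if (all(w == 0))
    stop("estimate_generalized_filter: flat profile, no signal above baseline")
  generalized_filter(w, delta = delta)
}
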