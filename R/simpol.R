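#' SimPol simulator configuration
#'
#' SimPol tracks the independent movement of RNA polymerases along a gene in
#' each of many cells, in discrete time slices. A polymerase at site i
#' advances one nucleotide per slice with probability
#' `zeta_bar * zeta[i] * time_slice`, unless another polymerase blocks its
#' forward progress (within `footprint` nucleotides); a new polymerase
#' initiates at the first site with probability `alpha * time_slice` when the
#' start of the gene is free; polymerases reaching the end leave. Pause-escape
#' and premature termination are not modeled: the simulator targets gene-body
#' elongation.
#'
#' Units: `alpha` is an absolute initiation rate (events/min), `zeta_bar` an
#' absolute per-site stepping rate (nt/min; 2000 nt/min corresponds to the
#' typical 2 kb/min mammalian elongation rate) and `zeta` the dimensionless
#' local rate multiplier.
#'
#' @param gene_length gene length in nucleotides.
#' @param n_cells number of independent cells.
#' @param alpha initiation rate, events per minute.
#' @param zeta per-site relative elongation rate (length `gene_length`), or
#'   NULL for a constant rate of 1.
#' @param zeta_bar average stepping rate in nt/min.
#' @param time_slice slice duration in minutes (default 1e-4).
#' @param total_time simulated time in minutes (default 20, by which gene-body
#'   occupancy has equilibrated for genes of ~10 kb).
#' @param footprint nucleotides of exclusion between consecutive polymerases.
#' @param seed integer seed; NULL draws one from the session RNG.
#' @return An object of class `elr_simpol_config`.
#' @export
simpol_config <- function(gene_length, n_cells = 5000, alpha = 1,
                          zeta = NULL, zeta_bar = 2000,
                          time_slice = 1e-4, total_time = 20,
                          footprint = 1L, seed = NULL) {
  if (is.null(zeta)) zeta <- rep(1, gene_length)
  stopifnot(length(zeta) == gene_length, all(zeta >= 0), alpha >= 0,
            zeta_bar >= 0, time_slice > 0, total_time > 0, footprint >= 1)
  if (zeta_bar * max(zeta) * time_slice > 1)
    stop("simpol_config: per-slice move probability exceeds 1; ",
         "reduce time_slice or rates")
  if (alpha * time_slice > 1)
    stop("simpol_config: per-slice initiation probability exceeds 1")
  structure(list(gene_length = as.integer(gene_length),
                 n_cells = as.integer(n_cells), alpha = alpha,
                 zeta = as.numeric(zeta), zeta_bar = zeta_bar,
                 time_slice = time_slice, total_time = total_time,
                 footprint = as.integer(footprint), seed = seed),
            class = "elr_simpol_config")
}

#' Simulate steady-state polymerase occupancy
#'
#' Runs SimPol and returns the empirical polymerase density per nucleotide,
#' averaged across cells and across the second half of the simulated time
#' (the first half is discarded as equilibration; `window = "snapshot"`
#' instead records the final slice only). In the rare-collision regime the
#' expected occupancy follows the steady-state law: proportional to
#' `alpha / (zeta_bar * zeta[i])`.
#'
#' The `"event"` method draws one geometric waiting time per site visit and
#' is exactly equivalent in distribution to the literal `"slice"` iteration
#' (which is retained as a reference implementation); both use the same
#' start-of-slice blocking convention.
#'
#' @param config an [simpol_config()].
#' @param method `"event"` (fast, default) or `"slice"` (literal reference).
#' @param window `"average"` (time-average over the equilibrated second half)
#'   or `"snapshot"` (final slice).
#' @return Numeric vector of per-site occupancy (values in [0, 1]).
#' @export
simulate_occupancy <- function(config, method = c("event", "slice"),
                               window = c("average", "snapshot")) {
  method <- match.arg(method)
  window <- match.arg(window)
  stopifnot(inherits(config, "elr_simpol_config"))
  p_move <- config$zeta_bar * config$zeta * config$time_slice
  p_init <- config$alpha * config$time_slice
  n_slices <- round(config$total_time / config$time_slice)
  win_start <- if (window == "average") floor(n_slices / 2) + 1 else n_slices
  seed <- if (is.null(config$seed)) sample.int(.Machine$integer.max, 1L)
          else config$seed
  fn <- if (method == "event") simpol_event_cpp else simpol_slice_cpp
  fn(p_move, p_init, config$n_cells, config$footprint,
     as.numeric(win_start), as.numeric(n_slices), as.numeric(seed))
}

#' Sample synthetic NRS read counts from an occupancy profile
#'
#' Read counts are Poisson, proportional to the polymerase density:
#' `X_i ~ Pois(scale * occupancy_i)`. The scale is chosen so the mean
#' expected count equals `target_depth` (per nucleotide), emulating a
#' sequencing experiment at a given depth; alternatively an explicit `scale`
#' can be shared across genes so that gene-level depths vary with their
#' initiation rates.
#'
#' @param occupancy non-negative per-site density.
#' @param target_depth desired mean read depth (reads per nucleotide).
#' @param scale explicit Poisson scale (overrides `target_depth`).
#' @param seed optional seed.
#' @return Integer vector of read counts.
#' @export
sample_reads <- function(occupancy, target_depth = NULL, scale = NULL,
                         seed = NULL) {
  if (any(occupancy < 0)) stop("sample_reads: negative occupancy")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scale)) {
    if (is.null(target_depth))
      stop("sample_reads: give target_depth or scale")
    if (target_depth == 0) return(integer(length(occupancy)))
    if (all(occupancy == 0))
      stop("sample_reads: all-zero occupancy")
    scale <- target_depth / mean(occupancy)
  }
  rpois(length(occupancy), scale * occupancy)
}

# ---- synthetic covariates ------------------------------------------------

#' Default epigenomic feature set for synthetic benchmarks
#'
#' Six features emulating the covariates used in the epigenomic validation:
#' a CTCF-binding track, four histone marks and an RNA stem-loop track, with
#' coefficients matching estimates from K562 nascent-RNA data (negative
#' values slow elongation; H3K79me2 speeds it up) and a block-level
#' correlation structure in which histone marks are moderately mutually
#' correlated.
#'
#' @return A list with `names`, `kappa` (named coefficient vector) and
#'   `correlation` (6 x 6 matrix).
#' @export
default_epigenomic_features <- function() {
  nm <- c("CTCF", "H3K36me3", "H3K9me1", "H4K20me1", "H3K79me2", "stem_loop")
  kappa <- c(CTCF = -0.022, H3K36me3 = -0.095, H3K9me1 = -0.067,
             H4K20me1 = -0.041, H3K79me2 = 0.030, stem_loop = -0.051)
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  marks <- c("H3K36me3", "H3K9me1", "H4K20me1", "H3K79me2")
  R[marks, marks] <- 0.4
  diag(R) <- 1
  R["stem_loop", marks] <- R[marks, "stem_loop"] <- 0.2
  R["CTCF", marks] <- R[marks, "CTCF"] <- 0.1
  list(names = nm, kappa = kappa, correlation = R)
}

#' Synthetic library of correlated covariate blocks
#'
#' Emulates block-sampling of real epigenomic tracks: covariate values are
#' constant within 1-kb blocks, and block values are drawn jointly from a
#' latent Gaussian field with a target correlation matrix, so tiling blocks
#' preserves the between-feature correlation structure of the library.
#'
#' @param n_blocks number of blocks in the library.
#' @param block_size block length in nucleotides (default 1000).
#' @param correlation feature correlation matrix (default:
#'   [default_epigenomic_features()]).
#' @param names feature names.
#' @param seed optional seed.
#' @return An object of class `elr_block_library`.
#' @export
synthetic_block_library <- function(n_blocks = 500, block_size = 1000,
                                    correlation = NULL, names = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(correlation)) {
    def <- default_epigenomic_features()
    correlation <- def$correlation
    if (is.null(names)) names <- def$names
  }
  F <- ncol(correlation)
  if (is.null(names)) names <- colnames(correlation)
  if (is.null(names)) names <- paste0("f", seq_len(F))
  L <- chol(correlation)
  vals <- matrix(rnorm(n_blocks * F), n_blocks, F) %*% L
  colnames(vals) <- names
  structure(list(values = vals, block_size = as.integer(block_size),
                 names = names),
            class = "elr_block_library")
}

#' Sample per-nucleotide covariates by tiling library blocks
#'
#' Blocks are sampled with replacement from the library and tiled jointly
#' across features to the requested length (the last block is truncated), so
#' the output preserves the library's block-level correlation structure.
#'
#' @param block_library an [synthetic_block_library()] (or an object with a
#'   `values` matrix of block values and a `block_size`).
#' @param n_sites output length in nucleotides.
#' @param seed optional seed.
#' @return Numeric matrix `n_sites` x features.
#' @export
sample_covariates <- function(block_library, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(block_library$values)
  if (is.null(nb) || nb == 0) stop("sample_covariates: empty block library")
  bs <- block_library$block_size
  need <- ceiling(n_sites / bs)
  pick <- if (nb == 1L) rep(1L, need) else sample.int(nb, need, replace = TRUE)
  out <- block_library$values[rep(pick, each = bs), , drop = FALSE][
    seq_len(n_sites), , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- block_library$names
  out
}

#' Local elongation rates from covariates under the generative GLM
#'
#' \eqn{\zeta_i = \exp(\kappa\cdot Y_i) + \delta_i}, with
#' \eqn{\delta_i \sim N(0, \mathrm{noise\_sd}^2)} and a small positive floor
#' (default 1e-3) since the additive Gaussian noise can otherwise produce
#' non-positive rates. `noise_sd = 0` gives the exact GLM surface.
#'
#' @param kappa coefficient vector.
#' @param features standardized [feature_matrix()] (or a plain matrix /
#'   list of matrices of standardized values).
#' @param noise_sd standard deviation of the additive rate noise (the
#'   epigenomic benchmark uses 0.1).
#' @param seed optional seed.
#' @param floor lower truncation for the rates.
#' @return List of per-TU \eqn{\zeta} vectors (a single vector input returns
#'   a list of length 1).
#' @export
make_zeta <- function(kappa, features, noise_sd = 0.1, seed = NULL,
                      floor = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  values <- if (inherits(features, "elr_features")) features$values
            else if (is.matrix(features)) list(features) else features
  lapply(values, function(Y) {
    z <- exp(as.numeric(Y %*% kappa))
    if (noise_sd > 0) z <- z + rnorm(length(z), 0, noise_sd)
    pmax(z, floor)
  })
}
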