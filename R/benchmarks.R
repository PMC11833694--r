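# Synthetic validation benchmarks: full generative pipelines (covariates ->
# rates -> SimPol occupancy -> Poisson reads) matching the two simulation
# studies used to validate the GLM. Defaults are the full study conditions
# (epigenomic: 10 replicates of 100 TUs x 10 kb in 5000 cells, rate noise
# sd 0.1; k-mer: 200 TUs per replicate, 100 true 5-mers with coefficients in
# [-0.3, 0.3], no rate noise); smaller runs are obtained by passing smaller
# sizes explicitly.

benchmark_alpha <- function(n_tus, meanlog = 0, sdlog = 1) {
  a <- rlnorm(n_tus, meanlog, sdlog)
  a / median(a)  # long-tailed initiation rates with median 1 event/min
}

#' Generate the epigenomic simulation benchmark
#'
#' Each replicate simulates TUs with six correlated block-sampled covariates
#' ([synthetic_block_library()]), local rates
#' \eqn{\zeta_i = \exp(\kappa\cdot Y_i) + \delta_i} with
#' \eqn{\delta_i \sim N(0, 0.1^2)} by default, gene-specific initiation
#' rates with median 1 event/min, SimPol occupancy simulation and Poisson
#' read sampling at a common per-replicate scale chosen to hit the target
#' mean depth. 20% of TUs are held out for testing.
#'
#' @param n_replicates,n_tus,tu_length,n_cells study dimensions (defaults:
#'   10 replicates of 100 TUs of 10 kb in 5000 cells).
#' @param depth target mean read depth, reads per nucleotide.
#' @param noise_sd rate noise standard deviation (0 for the noise-free
#'   variant).
#' @param kappa true coefficients (default [default_epigenomic_features()]).
#' @param correlation block correlation matrix (same default).
#' @param alpha_sdlog log-sd of the lognormal initiation-rate distribution.
#' @param zeta_bar,time_slice,total_time,footprint SimPol settings.
#' @param test_frac held-out fraction of TUs.
#' @param method occupancy sampler, `"event"` or `"slice"`.
#' @param seed optional seed for the whole generation.
#' @return A list of replicates (class `elr_benchmark`), each with elements
#'   `tus`, `features` (raw [feature_matrix()]), `zeta_true`, `kappa_true`,
#'   `alpha`, `train_idx`, `test_idx`, `type = "epigenomic"`.
#' @export
generate_epigenomic_benchmark <- function(n_replicates = 10, n_tus = 100,
                                          tu_length = 10000, n_cells = 5000,
                                          depth = 0.5, noise_sd = 0.1,
                                          kappa = NULL, correlation = NULL,
                                          alpha_sdlog = 1, zeta_bar = 2000,
                                          time_slice = 1e-4, total_time = 20,
                                          footprint = 1L, test_frac = 0.2,
                                          method = "event", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  def <- default_epigenomic_features()
  if (is.null(kappa)) kappa <- def$kappa
  if (is.null(correlation)) correlation <- def$correlation
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    lib <- synthetic_block_library(n_blocks = 500, block_size = 1000,
                                   correlation = correlation,
                                   names = names(kappa))
    values <- lapply(seq_len(n_tus), function(j)
      sample_covariates(lib, tu_length))
    fm_raw <- feature_matrix(values, names = names(kappa))
    fm_std <- standardize(fm_raw)
    zeta <- make_zeta(kappa, fm_std, noise_sd = noise_sd)
    alpha <- benchmark_alpha(n_tus, sdlog = alpha_sdlog)
    occ <- vector("list", n_tus)
    for (j in seq_len(n_tus)) {
      cfg <- simpol_config(tu_length, n_cells = n_cells, alpha = alpha[j],
                           zeta = zeta[[j]], zeta_bar = zeta_bar,
                           time_slice = time_slice, total_time = total_time,
                           footprint = footprint,
                           seed = sample.int(.Machine$integer.max, 1L))
      occ[[j]] <- simulate_occupancy(cfg, method = method)
    }
    scale <- depth / mean(unlist(occ, use.names = FALSE))
    tus <- lapply(seq_len(n_tus), function(j) {
      transcription_unit(sprintf("rep%d_tu%d", r, j), "synthetic", "+",
                         (j - 1) * (tu_length + 1000),
                         (j - 1) * (tu_length + 1000) + tu_length,
                         counts = sample_reads(occ[[j]], scale = scale))
    })
    test_idx <- sort(sample.int(n_tus, max(1L, round(test_frac * n_tus))))
    reps[[r]] <- structure(
      list(type = "epigenomic", tus = tus, features = fm_raw,
           zeta_true = zeta, kappa_true = kappa, alpha = alpha,
           occupancy = occ, depth = depth, noise_sd = noise_sd,
           train_idx = setdiff(seq_len(n_tus), test_idx),
           test_idx = test_idx),
      class = "elr_benchmark")
  }
  reps
}

#' Generate the 5-mer sequence simulation benchmark
#'
#' Each replicate simulates TUs with i.i.d.-uniform random DNA, assigns
#' nonzero coefficients (uniform in `[-kappa_max, kappa_max]`) to
#' `n_true_kmers` randomly chosen 5-mers and zero to the rest, sets
#' \eqn{\zeta_i = \exp(\kappa_{w(i)})} from the 5-mer at each site's active
#' site (no rate noise), and runs SimPol plus Poisson read sampling as in
#' [generate_epigenomic_benchmark()].
#'
#' @inheritParams generate_epigenomic_benchmark
#' @param n_true_kmers number of 5-mers with nonzero coefficients.
#' @param kappa_max coefficient range half-width.
#' @return A list of replicates (class `elr_benchmark`), each with `tus`,
#'   `seqs`, `features` (raw [kmer_features()]), `zeta_true`, `kappa_true`
#'   (named over all 1024 5-mers, on the raw indicator scale), `true_kmers`,
#'   `alpha`, `train_idx`, `test_idx`, `type = "kmer"`.
#' @export
generate_kmer_benchmark <- function(n_replicates = 10, n_tus = 200,
                                    tu_length = 10000, n_cells = 5000,
                                    depth = 0.5, n_true_kmers = 100,
                                    kappa_max = 0.3, alpha_sdlog = 1,
                                    zeta_bar = 2000, time_slice = 1e-4,
                                    total_time = 20, footprint = 1L,
                                    test_frac = 0.2, method = "event",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kmers5 <- all_kmers(5L)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seqs <- lapply(seq_len(n_tus), function(j)
      paste(sample(c("A", "C", "G", "T"), tu_length, replace = TRUE),
            collapse = ""))
    kf <- kmer_features(seqs, kmers = 5L)
    true_kmers <- sample(kmers5, n_true_kmers)
    kappa_true <- stats::setNames(numeric(length(kmers5)), kmers5)
    kappa_true[true_kmers] <- runif(n_true_kmers, -kappa_max, kappa_max)
    zg <- exp(as.numeric(kf$P %*% kappa_true))  # raw indicator scale
    zeta <- lapply(kf$gid, function(g) zg[g])
    alpha <- benchmark_alpha(n_tus, sdlog = alpha_sdlog)
    occ <- vector("list", n_tus)
    for (j in seq_len(n_tus)) {
      cfg <- simpol_config(tu_length, n_cells = n_cells, alpha = alpha[j],
                           zeta = zeta[[j]], zeta_bar = zeta_bar,
                           time_slice = time_slice, total_time = total_time,
                           footprint = footprint,
                           seed = sample.int(.Machine$integer.max, 1L))
      occ[[j]] <- simulate_occupancy(cfg, method = method)
    }
    scale <- depth / mean(unlist(occ, use.names = FALSE))
    tus <- lapply(seq_len(n_tus), function(j) {
      transcription_unit(sprintf("rep%d_tu%d", r, j), "synthetic", "+",
                         (j - 1) * (tu_length + 1000),
                         (j - 1) * (tu_length + 1000) + tu_length,
                         counts = sample_reads(occ[[j]], scale = scale))
    })
    test_idx <- sort(sample.int(n_tus, max(1L, round(test_frac * n_tus))))
    reps[[r]] <- structure(
      list(type = "kmer", tus = tus, seqs = seqs, features = kf,
           zeta_true = zeta, kappa_true = kappa_true,
           true_kmers = true_kmers, alpha = alpha, occupancy = occ,
           depth = depth,
           train_idx = setdiff(seq_len(n_tus), test_idx),
           test_idx = test_idx),
      class = "elr_benchmark")
  }
  reps
}

#' @export
print.elr_benchmark <- function(x, ...) {
  cat(sprintf("<elr_benchmark> %s: %d TU(s) (%d train / %d test), %d nt each\n",
              x$type, length(x$tus), length(x$train_idx), length(x$test_idx),
              tu_length(x$tus[[1]])))
  invisible(x)
}

#' Fit and evaluate a benchmark replicate
#'
#' Standardizes features with training-TU statistics, fits the GLM on the
#' training TUs (for the k-mer type: an L1 fit with the penalty chosen by
#' held-out AIC on an internal 80/20 gene split of the training TUs, then a
#' refit at the selected penalty on all training TUs), predicts per-site
#' relative rates on the held-out TUs and reports the pooled squared Pearson
#' correlation against the true rates.
#'
#' @param bench one replicate from [generate_epigenomic_benchmark()] or
#'   [generate_kmer_benchmark()].
#' @param nu_grid penalty grid for [select_nu()] (k-mer type; NULL = default
#'   data-driven grid).
#' @param tol,max_iter fitter settings.
#' @param seed seed for the internal AIC split.
#' @return A list with `fit` (training fit), `r2` (held-out pooled r^2 of
#'   predicted vs true zeta), `kappa` (fitted coefficients), and for the
#'   k-mer type `nu`, `nonzero` (selected k-mers) and `overlap` (fraction of
#'   true k-mers recovered).
#' @export
run_benchmark <- function(bench, nu_grid = NULL, tol = 1e-7,
                          max_iter = 20000L, seed = NULL) {
  stopifnot(inherits(bench, "elr_benchmark"))
  tr <- bench$train_idx
  te <- bench$test_idx
  if (bench$type == "epigenomic") {
    fm_std <- standardize(bench$features, stats_from = tr)
    fit <- fit_elongation_glm(bench$tus[tr], subset_features(fm_std, tr),
                              tol = tol, max_iter = max_iter)
    zhat <- predict_zeta(fit, subset_features(bench$features, te))
    r2 <- pooled_r2(zhat, bench$zeta_true[te])
    list(fit = fit, r2 = r2, kappa = fit$kappa)
  } else {
    kf_std <- standardize(bench$features, stats_from = tr)
    sel <- select_nu(bench$tus[tr], subset_features(kf_std, tr),
                     nu_grid = nu_grid, penalty = "l1", seed = seed,
                     tol = tol, max_iter = max_iter)
    fit <- fit_elongation_glm(bench$tus[tr], subset_features(kf_std, tr),
                              penalty = "l1", nu = sel$nu,
                              tol = tol, max_iter = max_iter)
    zhat <- predict_zeta(fit, subset_features(kf_std, te))
    r2 <- pooled_r2(zhat, bench$zeta_true[te])
    nz <- nonzero_coefficients(fit)
    list(fit = fit, r2 = r2, kappa = fit$kappa, nu = sel$nu,
         aic = sel$aic, nonzero = nz,
         overlap = length(intersect(nz, bench$true_kmers)) /
           length(bench$true_kmers))
  }
}

#' Pooled squared Pearson correlation between two sets of tracks
#'
#' @param predicted,truth lists of numeric vectors (same shapes); values are
#'   pooled across list elements before correlating.
#' @export
pooled_r2 <- function(predicted, truth) {
  p <- unlist(predicted, use.names = FALSE)
  t <- unlist(truth, use.names = FALSE)
  stopifnot(length(p) == length(t))
  stats::cor(p, t)^2
}
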