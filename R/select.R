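#' Select the L1 penalty strength by held-out AIC
#'
#' Genes are split 80/20 into training and testing sets once; for every
#' penalty value in the grid the model is fitted to the training genes and
#' the Akaike Information Criterion 2k - 2l is evaluated on the held-out
#' genes, where k counts coefficients with |kappa| above the zero threshold
#' (held-out chi parameters are re-optimized analytically on both arms and
#' therefore not counted) and l is the unpenalized held-out log likelihood
#' with chi re-optimized on the test genes. The penalty minimizing the
#' held-out AIC is returned together with its training fit.
#'
#' The default grid is data-driven, as in lasso-path solvers: log-spaced
#' from the smallest penalty that zeroes every coefficient (the sup-norm of
#' the gradient at kappa = 0) down by 10^-2.5.
#'
#' @param tus list of TUs (>= 5 genes with reads).
#' @param features [feature_matrix()] or [kmer_features()]; standardized
#'   internally over all supplied TUs if not already.
#' @param nu_grid numeric vector of candidate penalties (default: see
#'   above).
#' @param penalty passed to [fit_elongation_glm()] (default `"l1"`).
#' @param train_frac fraction of genes used for training.
#' @param seed optional seed for the split (the split is drawn once, so the
#'   AIC curve is evaluated on identical splits across the grid).
#' @param zero_threshold coefficients below this magnitude count as zero.
#' @param ... further arguments to [fit_elongation_glm()].
#' @return A list with `nu` (selected penalty), `fit` (training fit at the
#'   selected penalty), `aic` (data frame over the grid), `train_idx`,
#'   `test_idx`.
#' @export
select_nu <- function(tus, features, nu_grid = NULL, penalty = "l1",
                      train_frac = 0.8, seed = NULL,
                      zero_threshold = 1e-6, ...) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  M <- length(tus)
  if (M < 5L) stop("select_nu: need at least 5 genes")
  if (!is.null(seed)) set.seed(seed)
  feats <- if (isTRUE(features$standardized)) features else standardize(features)
  n_test <- max(1L, round((1 - train_frac) * M))
  test_idx <- sort(sample.int(M, n_test))
  train_idx <- setdiff(seq_len(M), test_idx)

  md_test <- glm_model_data(tus[test_idx], subset_features(feats, test_idx))

  if (is.null(nu_grid)) {
    md_tr <- glm_model_data(tus[train_idx], subset_features(feats, train_idx))
    chi0 <- update_chi(md_tr$s_j, md_tr$lambda, md_tr$N_j)
    st0 <- glm_stats_md(md_tr, numeric(md_tr$F), want_V = TRUE)
    g0 <- md_tr$lambda * as.numeric(crossprod(st0$V, chi0)) - md_tr$T_tot
    nu_max <- max(abs(g0))
    nu_grid <- nu_max * 10^seq(0, -2.5, length.out = 10)
  }
  if (length(nu_grid) == 0L) stop("select_nu: empty penalty grid")
  nu_grid <- sort(nu_grid, decreasing = TRUE)

  fits <- vector("list", length(nu_grid))
  aic <- ll <- nz <- numeric(length(nu_grid))
  kappa_warm <- NULL
  for (k in seq_along(nu_grid)) {
    fit <- fit_elongation_glm(tus[train_idx],
                              subset_features(feats, train_idx),
                              penalty = penalty, nu = nu_grid[k],
                              init_kappa = kappa_warm, keep_trace = FALSE,
                              ...)
    kappa_warm <- fit$kappa
    st <- glm_stats_md(md_test, fit$kappa)
    chi_t <- update_chi(md_test$s_j, fit$lambda, st$U)
    pos <- md_test$s_j > 0
    ll[k] <- sum(md_test$s_j[pos] * log(chi_t[pos])) -
      sum(fit$kappa * md_test$T_tot) -
      fit$lambda * sum(chi_t * st$U) + md_test$xo_sum
    nz[k] <- sum(abs(fit$kappa) > zero_threshold)
    aic[k] <- 2 * nz[k] - 2 * ll[k]
    fits[[k]] <- fit
  }
  best <- which.min(aic)
  list(nu = nu_grid[best], fit = fits[[best]],
       aic = data.frame(nu = nu_grid, aic = aic, ll_test = ll,
                        nonzero = nz),
       train_idx = train_idx, test_idx = test_idx)
}

#' Batch-resampled fit with coefficient standard errors
#'
#' Repeats the fit on `n_batches` random gene subsets and reports the mean
#' coefficient vector with the across-batch standard deviation as standard
#' error (the strategy used at genome scale: e.g. 2000 genes in each of 10
#' rounds). With a single batch the SE is undefined and reported as NA.
#'
#' @param tus list of TUs.
#' @param features covariates (standardized once over all TUs if needed, so
#'   batch variation reflects gene resampling only).
#' @param n_batches number of resampling rounds.
#' @param batch_size genes per round (must not exceed the number of genes;
#'   default: all genes, i.e. pure refitting).
#' @param seed optional seed.
#' @param ... further arguments to [fit_elongation_glm()].
#' @return An `elr_glm_fit` whose `kappa` is the across-batch mean, with
#'   `se` (per coefficient) and `batch_kappa` (matrix batches x features)
#'   attached; `chi` is taken from a final fit on all genes.
#' @export
fit_batches <- function(tus, features, n_batches = 10, batch_size = NULL,
                        seed = NULL, ...) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  M <- length(tus)
  if (is.null(batch_size)) batch_size <- M
  if (batch_size > M)
    stop("fit_batches: batch_size exceeds the number of genes")
  if (!is.null(seed)) set.seed(seed)
  feats <- if (isTRUE(features$standardized)) features else standardize(features)
  kap <- NULL
  for (b in seq_len(n_batches)) {
    idx <- sort(sample.int(M, batch_size))
    fit_b <- fit_elongation_glm(tus[idx], subset_features(feats, idx),
                                keep_trace = FALSE, ...)
    kap <- rbind(kap, fit_b$kappa)
  }
  full <- fit_elongation_glm(tus, feats, keep_trace = FALSE, ...)
  full$kappa <- colMeans(kap)
  full$se <- if (n_batches > 1) apply(kap, 2, sd) else
    stats::setNames(rep(NA_real_, ncol(kap)), colnames(kap))
  full$batch_kappa <- kap
  full
}
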