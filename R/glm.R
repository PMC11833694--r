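# Poisson GLM for local elongation rates.
#
# Model: X_ij ~ Pois(lambda * chi_j / zeta_ij), zeta_ij = exp(kappa . Y_ij),
# with chi_j a free per-gene compound parameter and lambda the average read
# depth over all analyzed sites. Dropping terms constant in the parameters,
# the joint log likelihood is
#   l = sum_j [ s_j log chi_j - kappa . T_j - lambda chi_j U_j ]
# with sufficient statistics s_j = sum_i X_ij, T_j = sum_i X_ij Y_ij,
# U_j = sum_i exp(-kappa . Y_ij), V_j = sum_i exp(-kappa . Y_ij) Y_ij.
# kappa is fitted by (penalized) gradient ascent while chi_j is fully
# re-optimized analytically (chi_j = s_j / (lambda U_j)) on every iteration.
# The optional 3'-nucleotide sequence-bias extension multiplies each Poisson
# mean by rho_b = 4 pi_b for the base at the read 3' end, which adds
# sum_i X_i log rho_i to the likelihood and turns U_j into
# U'_j = sum_i rho_i exp(-kappa . Y_ij).

# ---- internal model-data builders ---------------------------------------

site_offsets <- function(seq_bias, seqs, tus) {
  rho <- seq_bias$rho
  lapply(seq_along(tus), function(j) {
    b <- strsplit(seqs[[j]], "")[[1]]
    o <- numeric(length(b))
    known <- b %in% names(rho)
    if (any(rho[b[known]] == 0 & tus[[j]]$counts[known] > 0))
      stop("sequence bias: zero frequency for a base with nonzero counts")
    o[known] <- log(rho[b[known]])
    o
  })
}

glm_model_data <- function(tus, features, seq_bias = NULL, seqs = NULL) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  M <- length(tus)
  masks <- lapply(tus, `[[`, "mask")
  counts <- lapply(tus, `[[`, "counts")
  s_j <- vapply(seq_len(M), function(j) sum(counts[[j]][masks[[j]]]), 0)
  N_j <- vapply(masks, sum, 0L)
  lambda <- sum(s_j) / sum(N_j)
  offs <- NULL
  if (!is.null(seq_bias)) {
    if (inherits(features, "elr_kmer_features")) {
      rho5 <- c(seq_bias$rho[c("A", "C", "G", "T")], 0)
      o_g <- ifelse(features$central_base == 4L, 0,
                    log(pmax(rho5[features$central_base + 1L], .Machine$double.xmin)))
      if (any(seq_bias$rho == 0))
        stop("sequence bias: zero base frequency not supported")
    } else {
      if (is.null(seqs))
        stop("sequence bias with dense features requires `seqs`")
      offs <- site_offsets(seq_bias, seqs, tus)
    }
  }

  if (inherits(features, "elr_kmer_features")) {
    kf <- if (features$standardized) features else standardize(features)
    stopifnot(length(kf$gid) == M)
    n_gj <- kmer_group_counts(kf, masks = masks)
    x_g <- rowSums(kmer_group_counts(kf, masks = masks, weights = counts))
    Traw <- as.numeric(Matrix::crossprod(kf$P, x_g))
    T_tot <- (Traw - kf$center * sum(s_j)) / kf$scale
    o_g <- if (is.null(seq_bias)) numeric(length(kf$codes)) else o_g
    xo_sum <- sum(x_g * o_g)
    trip <- Matrix::mat2triplet(kf$P)
    list(kind = "grouped", M = M, F = length(kf$names),
         feature_names = kf$names, center = kf$center, scale = kf$scale,
         s_j = s_j, N_j = N_j, lambda = lambda, T_tot = T_tot,
         n_gj = n_gj, Pi = trip$i - 1L, Pj = trip$j - 1L, Px = trip$x,
         G = length(kf$codes), o_g = o_g, xo_sum = xo_sum,
         gid = kf$gid, masks = masks)
  } else {
    fm <- if (features$standardized) features else standardize(features)
    stopifnot(length(fm$values) == M)
    for (j in seq_len(M))
      if (nrow(fm$values[[j]]) != tu_length(tus[[j]]))
        stop("features/TU length mismatch for '", tus[[j]]$id, "'")
    Y <- do.call(rbind, lapply(seq_len(M), function(j)
      fm$values[[j]][masks[[j]], , drop = FALSE]))
    x <- unlist(lapply(seq_len(M), function(j) counts[[j]][masks[[j]]]),
                use.names = FALSE)
    gene <- rep.int(seq_len(M) - 1L, N_j)
    off <- if (is.null(offs)) numeric(length(x)) else
      unlist(lapply(seq_len(M), function(j) offs[[j]][masks[[j]]]),
             use.names = FALSE)
    T_tot <- as.numeric(crossprod(Y, x))
    list(kind = "dense", M = M, F = ncol(Y),
         feature_names = fm$names, center = fm$center, scale = fm$scale,
         s_j = s_j, N_j = N_j, lambda = lambda, T_tot = T_tot,
         Y = Y, x = x, gene = gene, offset = off, xo_sum = sum(x * off))
  }
}

# U_j and V_j (and per-gene T_j) at a given kappa, from model data. V is
# returned only if `want_V`; cost O(sites x features) dense, O(groups) grouped.
glm_stats_md <- function(md, kappa, want_V = FALSE) {
  if (md$kind == "dense") {
    q <- as.numeric(md$Y %*% kappa) - md$offset
    w <- exp(-q)
    U <- as.numeric(rowsum(w, md$gene, reorder = TRUE))
    V <- if (want_V) rowsum(md$Y * w, md$gene, reorder = TRUE) else NULL
    list(U = U, V = V)
  } else {
    ks <- kappa / md$scale
    cc <- sum(kappa * md$center / md$scale)
    qacc <- numeric(md$G)  # kappa_std . Y_raw per group
    if (length(md$Pi)) {
      acc <- rowsum(ks[md$Pj + 1L] * md$Px, md$Pi)
      qacc[as.integer(rownames(acc)) + 1L] <- acc[, 1]
    }
    w_g <- exp(cc + md$o_g - qacc)
    U <- as.numeric(crossprod(md$n_gj, w_g))
    V <- NULL
    if (want_V) {
      V <- matrix(0, md$M, md$F)
      for (j in seq_len(md$M)) {
        a <- md$n_gj[, j] * w_g
        raw <- numeric(md$F)
        if (length(md$Pi)) {
          contrib <- rowsum(a[md$Pi + 1L] * md$Px, md$Pj, reorder = FALSE)
          raw[as.integer(rownames(contrib)) + 1L] <- contrib[, 1]
        }
        V[j, ] <- (raw - md$center * sum(a)) / md$scale
      }
    }
    list(U = U, V = V)
  }
}

# ---- exported low-level operations --------------------------------------

#' Joint log likelihood of the elongation GLM
#'
#' Evaluates \eqn{\sum_j [s_j \log\chi_j - \kappa\cdot T_j - \lambda\chi_j
#' U_j]} (constants dropped), with the sequence-bias extension adding
#' \eqn{\sum_i X_i \log\rho_i} and weighting \eqn{U_j} by \eqn{\rho_i}.
#' Masked sites are excluded from all sums.
#'
#' @param tus TU or list of TUs with counts and masks.
#' @param features standardized [feature_matrix()] or [kmer_features()].
#' @param kappa coefficient vector (one per feature).
#' @param chi per-gene compound parameter(s), all > 0.
#' @param lambda read-depth scale (default 1).
#' @param seq_bias optional [estimate_seq_bias()] result.
#' @param seqs transcription-strand sequences, required for `seq_bias` with
#'   dense features.
#' @return The log likelihood (a scalar, up to data-dependent constants).
#' @export
log_likelihood <- function(tus, features, kappa, chi, lambda = 1,
                           seq_bias = NULL, seqs = NULL) {
  md <- glm_model_data(tus, features, seq_bias, seqs)
  if (any(chi <= 0)) stop("log_likelihood: chi must be positive")
  st <- glm_stats_md(md, kappa)
  sum(md$s_j * log(chi)) - sum(kappa * md$T_tot) -
    lambda * sum(chi * st$U) + md$xo_sum
}

#' Gradient of the (penalized) log likelihood with respect to kappa
#'
#' Component n is \eqn{\lambda\sum_j \chi_j V_{j,n} - T_{j,n} - \nu\,
#' \mathrm{sgn}(\kappa_n)} with sgn(0) = 0.
#'
#' @inheritParams log_likelihood
#' @param nu L1 penalty strength (0 = unpenalized).
#' @return Numeric gradient vector, named by feature.
#' @export
gradient_kappa <- function(tus, features, kappa, chi, nu = 0, lambda = 1,
                           seq_bias = NULL, seqs = NULL) {
  md <- glm_model_data(tus, features, seq_bias, seqs)
  st <- glm_stats_md(md, kappa, want_V = TRUE)
  g <- lambda * as.numeric(crossprod(st$V, chi)) - md$T_tot - nu * sign(kappa)
  if (!all(is.finite(g)))
    stop("gradient_kappa: non-finite gradient for feature '",
         md$feature_names[which(!is.finite(g))[1]], "'")
  stats::setNames(g, md$feature_names)
}

#' Analytic per-gene update of the compound parameter chi
#'
#' For fixed kappa the likelihood is maximized at
#' \eqn{\hat\chi_j = s_j / (\lambda U_j)}. Genes with no reads get
#' \eqn{\hat\chi_j = 0} (they carry no information and are excluded from
#' fitting).
#'
#' @param s_j per-gene read-count totals.
#' @param lambda read-depth scale (> 0).
#' @param U_j per-gene \eqn{U_j = \sum_i e^{-\kappa\cdot Y_{i,j}}} (> 0).
#' @return \eqn{\hat\chi_j}, vectorized over genes.
#' @export
update_chi <- function(s_j, lambda, U_j) {
  if (any(U_j <= 0)) stop("update_chi: U_j must be positive")
  if (lambda <= 0) stop("update_chi: lambda must be positive")
  ifelse(s_j > 0, s_j / (lambda * U_j), 0)
}

#' Per-gene sufficient statistics of the elongation GLM
#'
#' Returns \eqn{s_j}, \eqn{T_j}, \eqn{U_j} and \eqn{V_j} at the given kappa,
#' computed directly on the dense standardized covariate matrices. For
#' grouped k-mer features this expands the dense matrices and is intended for
#' verification at small scale; [sufficient_stats_sparse()] computes the same
#' quantities from the raw sparse values.
#'
#' @inheritParams log_likelihood
#' @return A list with `s` (per gene), `T` (genes x features), `U` (per
#'   gene), `V` (genes x features).
#' @export
sufficient_stats <- function(tus, features, kappa, seq_bias = NULL,
                             seqs = NULL) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  fm <- if (inherits(features, "elr_kmer_features"))
    as_dense_features(if (features$standardized) features else standardize(features))
  else (if (features$standardized) features else standardize(features))
  offs <- if (is.null(seq_bias)) NULL else site_offsets(seq_bias, seqs, tus)
  M <- length(tus)
  Tm <- V <- matrix(0, M, n_features(fm))
  U <- s <- numeric(M)
  for (j in seq_len(M)) {
    keep <- tus[[j]]$mask
    Y <- fm$values[[j]][keep, , drop = FALSE]
    x <- tus[[j]]$counts[keep]
    o <- if (is.null(offs)) 0 else offs[[j]][keep]
    w <- exp(-(as.numeric(Y %*% kappa) - o))
    s[j] <- sum(x)
    Tm[j, ] <- as.numeric(crossprod(Y, x))
    U[j] <- sum(w)
    V[j, ] <- as.numeric(crossprod(Y, w))
  }
  colnames(Tm) <- colnames(V) <- fm$names
  list(s = s, T = Tm, U = U, V = V)
}

#' Sufficient statistics via the sparse linear-transformation path
#'
#' Computes \eqn{U_j} and \eqn{V_j} for standardized k-mer indicator features
#' without ever forming the dense standardized matrix: the exponent satisfies
#' \eqn{\kappa\cdot Y^{std}_i = (\kappa/s)\cdot Y^{raw}_i - \sum_n \kappa_n
#' m_n/s_n}, so everything reduces to the sparse raw values plus the stored
#' standardization statistics. Results agree with [sufficient_stats()] to
#' floating-point accuracy at a cost proportional to the nonzero raw entries.
#'
#' @param tus TU or list of TUs.
#' @param kf a standardized [kmer_features()] object (raw values + stats).
#' @param kappa coefficient vector.
#' @return A list with `U` (per gene) and `V` (genes x features).
#' @export
sufficient_stats_sparse <- function(tus, kf, kappa) {
  stopifnot(inherits(kf, "elr_kmer_features"))
  if (!kf$standardized)
    stop("sufficient_stats_sparse: standardization stats missing; ",
         "call standardize() first")
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  md <- glm_model_data(tus, kf)
  st <- glm_stats_md(md, kappa, want_V = TRUE)
  colnames(st$V) <- md$feature_names
  list(U = st$U, V = st$V)
}

#' Read-count-weighted 3'-nucleotide composition (sequence bias)
#'
#' Estimates the bulk distribution \eqn{\pi_b} of bases at read 3' ends
#' (i.e. at the polymerase active sites), weighting each site by its read
#' count, and the derived per-base scale factors \eqn{\rho_b = 4\pi_b} used
#' by the sequence-bias model variant. With uniform \eqn{\pi}, all
#' \eqn{\rho_b = 1} and the biased model collapses to the original one.
#'
#' @param tus TU or list of TUs with counts.
#' @param seqs transcription-strand sequences parallel to `tus`.
#' @return An object of class `elr_seq_bias` with elements `pi` and `rho`.
#' @export
estimate_seq_bias <- function(tus, seqs) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  if (is.character(seqs)) seqs <- as.list(seqs)
  tot <- c(A = 0, C = 0, G = 0, T = 0)
  for (j in seq_along(tus)) {
    b <- strsplit(seqs[[j]], "")[[1]]
    x <- tus[[j]]$counts * tus[[j]]$mask
    for (base in names(tot)) tot[base] <- tot[base] + sum(x[b == base])
  }
  if (sum(tot) == 0) stop("estimate_seq_bias: no reads at A/C/G/T sites")
  pi_b <- tot / sum(tot)
  structure(list(pi = pi_b, rho = 4 * pi_b), class = "elr_seq_bias")
}

#' @export
print.elr_seq_bias <- function(x, ...) {
  cat("<elr_seq_bias> pi:", paste(sprintf("%s=%.3f", names(x$pi), x$pi),
                                  collapse = " "), "\n")
  invisible(x)
}

# ---- fitting -------------------------------------------------------------

#' Fit the elongation-rate GLM by penalized gradient ascent
#'
#' Maximizes the joint Poisson log likelihood over the shared coefficients
#' kappa, re-optimizing the per-gene compound parameters chi analytically on
#' every iteration. The per-gene totals \eqn{s_j} and \eqn{T_j} are computed
#' once in preprocessing; \eqn{U_j} and \eqn{V_j} are recomputed per
#' iteration (via the grouped sparse path for k-mer features). Iteration
#' stops when the largest coefficient change drops below `tol` or after
#' `max_iter` iterations; the objective trace is non-decreasing because a
#' step that lowers it is rejected and the learning rate halved.
#'
#' @param tus list of [transcription_unit()] with counts and masks. Genes
#'   with zero (unmasked) reads are excluded with a warning.
#' @param features [feature_matrix()] or [kmer_features()]; standardized
#'   internally (statistics over all supplied TUs) if not already.
#' @param penalty `"none"`, `"l1"` (lasso, the default variant used for
#'   high-dimensional k-mer models), `"l2"` (ridge) or `"elasticnet"`.
#' @param nu penalty strength (ignored for `"none"`).
#' @param mixing elastic-net mixing (fraction of `nu` on the L1 term).
#' @param learning_rate `"auto"` (reciprocal of the total analyzed read
#'   count, which reproduces the order of 1e-7 at genome scale) or a numeric
#'   step size.
#' @param tol convergence threshold on max |delta kappa|.
#' @param max_iter maximum gradient-ascent iterations.
#' @param seq_bias optional [estimate_seq_bias()] result (3'-base bias
#'   variant).
#' @param seqs transcription-strand sequences (needed for `seq_bias` with
#'   dense features).
#' @param init_kappa starting coefficients (default all zero).
#' @param keep_trace store the objective trace (default TRUE).
#' @return An object of class `elr_glm_fit` with elements `kappa`, `chi`,
#'   `lambda`, `nu`, `penalty`, `objective` (trace), `n_iter`, `converged`,
#'   `learning_rate`, `center`, `scale` and `se` (filled by
#'   [fit_batches()]).
#' @seealso [select_nu()], [predict_zeta()], [fit_batches()]
#' @export
fit_elongation_glm <- function(tus, features,
                               penalty = c("none", "l1", "l2", "elasticnet"),
                               nu = 0, mixing = 0.5,
                               learning_rate = "auto",
                               tol = 1e-8, max_iter = 50000L,
                               seq_bias = NULL, seqs = NULL,
                               init_kappa = NULL, keep_trace = TRUE) {
  penalty <- match.arg(penalty)
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  ids <- vapply(tus, `[[`, "", "id")
  s_all <- vapply(tus, function(t) sum(t$counts[t$mask]), 0)
  if (all(s_all == 0)) stop("fit_elongation_glm: no gene has any reads")
  if (any(s_all == 0)) {
    warning("excluding ", sum(s_all == 0), " gene(s) with zero reads")
    keep_tu <- which(s_all > 0)
  } else keep_tu <- seq_along(tus)

  feats_sub <- subset_features(features, keep_tu)
  seqs_sub <- if (is.null(seqs)) NULL else seqs[keep_tu]
  md <- glm_model_data(tus[keep_tu], feats_sub, seq_bias, seqs_sub)

  nu1 <- nu2 <- 0
  if (penalty == "l1") nu1 <- nu
  else if (penalty == "l2") nu2 <- nu
  else if (penalty == "elasticnet") { nu1 <- mixing * nu; nu2 <- (1 - mixing) * nu }

  lr <- if (identical(learning_rate, "auto")) 1 / sum(md$s_j)
        else as.numeric(learning_rate)
  kappa0 <- if (is.null(init_kappa)) numeric(md$F) else {
    stopifnot(length(init_kappa) == md$F)
    as.numeric(init_kappa)
  }

  res <- if (md$kind == "dense")
    glm_ascent_dense_cpp(md$Y, md$gene, md$x, md$offset, md$s_j, md$T_tot,
                         md$lambda, nu1, nu2, kappa0, lr, tol,
                         as.integer(max_iter), md$xo_sum)
  else
    glm_ascent_grouped_cpp(md$Pi, md$Pj, md$Px, as.integer(md$G),
                           as.integer(md$F), md$center, md$scale, md$n_gj,
                           md$o_g, md$s_j, md$T_tot, md$lambda, nu1, nu2,
                           kappa0, lr, tol, as.integer(max_iter), md$xo_sum)

  chi <- stats::setNames(numeric(length(tus)), ids)
  chi[keep_tu] <- res$chi
  structure(list(
    kappa = stats::setNames(res$kappa, md$feature_names),
    chi = chi, lambda = md$lambda, nu = nu, penalty = penalty,
    objective = if (keep_trace) res$objective else tail(res$objective, 1),
    n_iter = res$n_iter, converged = res$converged,
    learning_rate = res$lr, center = md$center, scale = md$scale,
    feature_kind = md$kind, se = NULL),
    class = "elr_glm_fit")
}

#' @export
print.elr_glm_fit <- function(x, ...) {
  cat(sprintf(paste0("<elr_glm_fit> %d feature(s), %d gene(s), penalty=%s",
                     " (nu=%g)\n  %s after %d iterations; lambda=%.4g; ",
                     "%d nonzero coefficient(s)\n"),
              length(x$kappa), length(x$chi), x$penalty, x$nu,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$lambda, sum(abs(x$kappa) > 1e-6)))
  invisible(x)
}

#' Number of effectively nonzero coefficients of a fit
#'
#' Coefficients with |kappa| below the zero threshold (1e-6) are treated as
#' exactly zero, the convention used for AIC parameter counts and sparsity
#' reports.
#'
#' @param fit an `elr_glm_fit`.
#' @param threshold zero threshold.
#' @export
nonzero_coefficients <- function(fit, threshold = 1e-6) {
  names(fit$kappa)[abs(fit$kappa) > threshold]
}

#' Subset a feature object to a set of TUs
#'
#' Keeps per-TU values for the selected TUs while preserving any attached
#' standardization statistics, so training-set statistics can be applied to
#' held-out TUs.
#'
#' @param features [feature_matrix()] or [kmer_features()].
#' @param idx integer indices of the TUs to keep.
#' @export
subset_features <- function(features, idx) {
  if (inherits(features, "elr_kmer_features")) {
    out <- features
    out$gid <- features$gid[idx]
    out
  } else {
    out <- features
    out$values <- features$values[idx]
    if (!is.null(features$defined)) out$defined <- features$defined[idx]
    out
  }
}

#' Predict per-nucleotide relative elongation rates
#'
#' \eqn{\hat\zeta_{i,j} = \exp(\hat\kappa\cdot Y_{i,j})} for every site of
#' every TU covered by `features`. Raw (unstandardized) features are
#' standardized with the statistics stored in the fit, so held-out data are
#' placed on the training scale.
#'
#' @param fit an `elr_glm_fit`.
#' @param features [feature_matrix()] or [kmer_features()] for the target
#'   TUs (raw or standardized).
#' @return A list of numeric vectors of \eqn{\hat\zeta}, one per TU.
#' @export
predict_zeta <- function(fit, features) {
  kappa <- fit$kappa
  if (inherits(features, "elr_kmer_features")) {
    idx <- match(names(kappa), features$names)
    if (anyNA(idx)) stop("predict_zeta: features missing fitted k-mers")
    ks <- kappa / fit$scale
    cc <- sum(kappa * fit$center / fit$scale)
    zg <- exp(as.numeric(features$P[, idx, drop = FALSE] %*% ks) - cc)
    lapply(features$gid, function(g) zg[g])
  } else {
    fm <- if (features$standardized) features else
      apply_standardization(features, fit$center, fit$scale)
    idx <- match(names(kappa), fm$names)
    if (anyNA(idx)) stop("predict_zeta: features missing fitted columns")
    lapply(fm$values, function(Y)
      exp(as.numeric(Y[, idx, drop = FALSE] %*% kappa)))
  }
}

#' Expected read counts for (possibly held-out) TUs
#'
#' The model's expected count at a site is \eqn{\lambda\chi_j/\zeta_{i,j}}.
#' For TUs not in the training set, \eqn{\chi_j} is obtained analytically
#' from their own read totals at the fitted kappa (Eq. for
#' \eqn{\hat\chi_j}), so predictions concern the distribution of reads
#' within each gene.
#'
#' @param fit an `elr_glm_fit`.
#' @param tus TUs to predict for.
#' @param features matching features (raw or standardized).
#' @return List of per-nucleotide expected counts, one vector per TU.
#' @export
predict_expected_counts <- function(fit, tus, features) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  zeta <- predict_zeta(fit, features)
  lapply(seq_along(tus), function(j) {
    tu <- tus[[j]]
    invz <- 1 / zeta[[j]]
    U <- sum(invz[tu$mask])
    chi <- update_chi(sum(tu$counts[tu$mask]), fit$lambda, U)
    fit$lambda * chi * invz
  })
}
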