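test_that("log likelihood matches hand evaluation and analytic chi", {
  tu <- transcription_unit("h", "c", "+", 0, 2, counts = c(1, 0))
  fm <- standardize(feature_matrix(matrix(c(-1, 1), 2, 1)))
  # kappa = 0 (zeta = 1), chi = 1: 1*log(1) - 0 - 1*2 = -2
  expect_equal(log_likelihood(tu, fm, 0, 1), -2)
  expect_error(log_likelihood(tu, fm, 0, -1), "positive")

  # with kappa = 0 the objective is maximized at chi = s/N (lambda = 1):
  # verified against a grid
  toy <- glm_toy(M = 1, n = 300, kappa = 0.1, seed = 2)
  s <- sum(toy$tus[[1]]$counts); N <- 300
  grid <- seq(0.2, 3, by = 0.001)
  ll <- vapply(grid, function(ch) log_likelihood(toy$tus, toy$features, 0, ch), 0)
  expect_equal(grid[which.max(ll)], s / N, tolerance = 2e-3)

  # doubling all counts doubles s and T and shifts the optimum accordingly
  tu2 <- toy$tus[[1]]; tu2$counts <- 2 * tu2$counts
  ll2 <- vapply(grid, function(ch) log_likelihood(list(tu2), toy$features, 0, ch), 0)
  expect_equal(grid[which.max(ll2)], 2 * s / N, tolerance = 4e-3)
})

test_that("analytic chi update equals 1-D maximization and handles edge cases", {
  expect_equal(update_chi(100, 1, 50), 2)
  expect_equal(update_chi(0, 1, 50), 0)
  expect_error(update_chi(10, 1, 0), "positive")
  toy <- glm_toy(M = 3, n = 400, seed = 3)
  kap <- rnorm(3, 0, 0.1)
  ss <- sufficient_stats(toy$tus, toy$features, kap)
  for (j in 1:3) {
    for (lam in c(1, 1.7)) {
      opt <- golden_max(function(ch) ss$s[j] * log(ch) - lam * ch * ss$U[j],
                        1e-8, 50)
      expect_lt(abs(update_chi(ss$s[j], lam, ss$U[j]) - opt), 1e-8)
    }
  }
})

test_that("gradient agrees with central finite differences", {
  toy <- glm_toy(M = 4, n = 500, kappa = c(-0.15, 0.08, 0.02), seed = 4)
  set.seed(9)
  for (rep in 1:5) {
    kap <- rnorm(3, 0, 0.15)
    chi <- runif(4, 0.3, 2.5)
    g <- gradient_kappa(toy$tus, toy$features, kap, chi)
    fd <- vapply(1:3, function(f) {
      e <- numeric(3); e[f] <- 1e-5
      (log_likelihood(toy$tus, toy$features, kap + e, chi) -
         log_likelihood(toy$tus, toy$features, kap - e, chi)) / 2e-5
    }, 0)
    expect_equal(unname(g), fd, tolerance = 1e-5)
    # L1 penalty shifts each component by exactly -nu * sgn(kappa)
    nu <- 3.7
    g_pen <- gradient_kappa(toy$tus, toy$features, kap, chi, nu = nu)
    expect_equal(unname(g - g_pen), nu * sign(kap))
  }
})

test_that("sparse-path sufficient statistics equal the dense computation", {
  seqs <- random_seqs(3, 400, seed = 6)
  tus <- make_tus(3, 400, lambda = 0.8, seed = 7)
  tus[[2]]$mask[50:120] <- FALSE  # masked sites must drop out of both paths
  for (kk in list(2L, "k<=5")) {
    # short sequences miss some 5-mers entirely; those constant indicator
    # columns are dropped with a warning, which is expected here
    kf <- suppressWarnings(standardize(kmer_features(seqs, kmers = kk)))
    kap <- rnorm(length(kf$names), 0, 0.05)
    sp <- sufficient_stats_sparse(tus, kf, kap)
    de <- sufficient_stats(tus, kf, kap)
    expect_lt(max(abs(sp$U - de$U)), 1e-10 * max(abs(de$U)))
    expect_lt(max(abs(sp$V - de$V)), 1e-10 * max(1, max(abs(de$V))))
  }
  # kappa = 0 gives U_j = number of unmasked sites
  kf <- standardize(kmer_features(seqs, 2L))
  sp0 <- sufficient_stats_sparse(tus, kf, numeric(length(kf$names)))
  expect_equal(sp0$U, vapply(tus, function(t) sum(t$mask), 0))
})

test_that("fitting recovers generative coefficients and ascends monotonically", {
  toy <- glm_toy(M = 6, n = 1500, kappa = c(-0.2, -0.08, 0.05), chi = rep(1.5, 6),
                 seed = 8)
  fit <- fit_elongation_glm(toy$tus, toy$features)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$kappa - toy$kappa)), 0.05)
  expect_true(all(diff(fit$objective) >= -1e-9))
  # objective at convergence is at least the kappa = 0 value
  md_chi <- update_chi(vapply(toy$tus, function(t) sum(t$counts), 0),
                       fit$lambda,
                       vapply(toy$tus, function(t) tu_length(t), 0))
  ll0 <- log_likelihood(toy$tus, toy$features, numeric(3), pmax(md_chi, 1e-12),
                        lambda = fit$lambda)
  expect_gte(tail(fit$objective, 1), ll0)
  # after convergence chi is coordinate-wise optimal: +/-1% perturbations hurt
  ss <- sufficient_stats(toy$tus, toy$features, fit$kappa)
  base <- log_likelihood(toy$tus, toy$features, fit$kappa, fit$chi,
                         lambda = fit$lambda)
  for (j in c(1, 4)) {
    for (fac in c(0.99, 1.01)) {
      chi2 <- fit$chi; chi2[j] <- chi2[j] * fac
      expect_lt(log_likelihood(toy$tus, toy$features, fit$kappa, chi2,
                               lambda = fit$lambda), base)
    }
  }
})

test_that("grouped and dense fitters give identical results", {
  seqs <- random_seqs(5, 600, seed = 10)
  kf <- kmer_features(seqs, 1L)
  kraw <- c(A = 0, C = -0.4, G = 0, T = 0.25)
  zg <- exp(as.numeric(kf$P %*% kraw))
  set.seed(11)
  tus <- lapply(1:5, function(j)
    transcription_unit(paste0("g", j), "c", "+", (j - 1) * 1200,
                       (j - 1) * 1200 + 600,
                       counts = rpois(600, 2 / zg[kf$gid[[j]]])))
  fit_g <- fit_elongation_glm(tus, standardize(kf), tol = 1e-10)
  fit_d <- fit_elongation_glm(tus, as_dense_features(kf), tol = 1e-10)
  expect_equal(fit_g$kappa, fit_d$kappa, tolerance = 1e-7)
  expect_equal(fit_g$chi, fit_d$chi, tolerance = 1e-7)
})

test_that("adding a constant to a raw feature leaves the fit unchanged", {
  toy <- glm_toy(M = 3, n = 600, kappa = c(-0.1, 0.07), seed = 12)
  raw <- lapply(1:3, function(j) matrix(rnorm(600 * 2), 600, 2))
  set.seed(13)
  counts <- lapply(1:3, function(j) rpois(600, 1))
  tus <- lapply(1:3, function(j)
    transcription_unit(paste0("g", j), "c", "+", (j - 1) * 1200,
                       (j - 1) * 1200 + 600, counts = counts[[j]]))
  f1 <- fit_elongation_glm(tus, feature_matrix(raw))
  shifted <- lapply(raw, function(Y) sweep(Y, 2, c(5, -2), "+"))
  f2 <- fit_elongation_glm(tus, feature_matrix(shifted))
  expect_equal(f1$kappa, f2$kappa, tolerance = 1e-8)
})

test_that("zero-read genes are flagged and excluded", {
  toy <- glm_toy(M = 3, n = 200, kappa = 0.1, seed = 14)
  toy$tus[[2]]$counts[] <- 0
  expect_warning(fit <- fit_elongation_glm(toy$tus, toy$features), "zero reads")
  expect_equal(unname(fit$chi[2]), 0)
  expect_true(fit$chi[1] > 0 && fit$chi[3] > 0)
})

test_that("uniform 3'-base composition reproduces the unbiased model bit-for-bit", {
  seqs <- random_seqs(3, 500, seed = 15)
  tus <- make_tus(3, 500, lambda = 1, seed = 16)
  kf <- standardize(kmer_features(seqs, 2L))
  kap <- rnorm(length(kf$names), 0, 0.03)
  chi <- c(1.2, 0.8, 1.5)
  bias_u <- structure(list(pi = c(A = .25, C = .25, G = .25, T = .25),
                           rho = c(A = 1, C = 1, G = 1, T = 1)),
                      class = "elr_seq_bias")
  ll_plain <- log_likelihood(tus, kf, kap, chi)
  ll_bias <- log_likelihood(tus, kf, kap, chi, seq_bias = bias_u, seqs = seqs)
  expect_identical(ll_plain, ll_bias)
  g_plain <- gradient_kappa(tus, kf, kap, chi)
  g_bias <- gradient_kappa(tus, kf, kap, chi, seq_bias = bias_u, seqs = seqs)
  expect_identical(g_plain, g_bias)
  f_plain <- fit_elongation_glm(tus, kf, max_iter = 200)
  f_bias <- fit_elongation_glm(tus, kf, max_iter = 200, seq_bias = bias_u,
                               seqs = seqs)
  expect_identical(f_plain$kappa, f_bias$kappa)
})

test_that("sequence-bias estimation and offsets behave as specified", {
  # rho_b = 4 pi_b; pi estimated read-count-weighted
  tu <- transcription_unit("g", "c", "+", 0, 8, counts = c(2, 0, 1, 1, 0, 0, 0, 4))
  sq <- "CCAATTGC"
  b <- estimate_seq_bias(tu, sq)
  expect_equal(sum(b$pi), 1)
  expect_equal(unname(b$pi["C"]), 6 / 8)  # 2 reads at pos1 + 4 at pos8
  expect_equal(unname(b$rho), unname(4 * b$pi))
  # pi_C = 0.4 -> offset -log(1.6) at C sites
  bias <- structure(list(pi = c(A = .2, C = .4, G = .2, T = .2),
                         rho = 4 * c(A = .2, C = .4, G = .2, T = .2)),
                    class = "elr_seq_bias")
  expect_equal(unname(bias$rho["C"]), 1.6)
  # biased likelihood = unbiased + sum X log rho when kappa = 0 has U' != U
  fm <- standardize(feature_matrix(matrix(rnorm(8), 8, 1)))
  ll_b <- log_likelihood(tu, fm, 0, 1, seq_bias = bias, seqs = sq)
  bases <- strsplit(sq, "")[[1]]
  expect_equal(ll_b,
               sum(tu$counts * log(bias$rho[bases])) - sum(bias$rho[bases]))
})

test_that("the biased fit shrinks 1-mer coefficients on composition-biased counts", {
  # counts carry a pure C/T 3'-end bias; the biased model absorbs it into rho
  set.seed(17)
  seqs <- random_seqs(6, 2000)
  kf <- kmer_features(seqs, 1L)
  rho_true <- c(A = 0.8, C = 1.6, G = 0.8, T = 0.8)
  tus <- lapply(1:6, function(j) {
    bases <- strsplit(seqs[[j]], "")[[1]]
    transcription_unit(paste0("g", j), "c", "+", (j - 1) * 4000,
                       (j - 1) * 4000 + 2000,
                       counts = rpois(2000, 2 * rho_true[bases]))
  })
  bias <- estimate_seq_bias(tus, seqs)
  expect_equal(unname(bias$rho["C"]), 1.6, tolerance = 0.1)
  kfs <- standardize(kf)
  fit_plain <- fit_elongation_glm(tus, kfs)
  fit_bias <- fit_elongation_glm(tus, kfs, seq_bias = bias, seqs = seqs)
  # unbiased fit sees a strong apparent C slowdown; biased fit removes it
  expect_lt(fit_plain$kappa["C"], -0.1)
  expect_lt(abs(fit_bias$kappa["C"]), 0.05)
})

test_that("predict_zeta applies training statistics to held-out raw features", {
  toy <- glm_toy(M = 4, n = 500, kappa = c(-0.12, 0.06), seed = 18)
  fit <- fit_elongation_glm(toy$tus[1:3],
                            standardize(toy$features, stats_from = 1:3))
  expect_equal(predict_zeta(fit, toy$features)[[4]],
               exp(as.numeric(toy$features$values[[4]] %*% fit$kappa)),
               tolerance = 1e-12)
  # kappa = 0 gives zeta identically 1
  fit0 <- fit
  fit0$kappa[] <- 0
  expect_equal(unique(unlist(predict_zeta(fit0, toy$features))), 1)
  # single negative coefficient at a +1-sd standardized site gives exp(-0.2)
  fit1 <- fit
  fit1$kappa <- c(f1 = -0.2, f2 = 0)
  fm1 <- feature_matrix(matrix(c(1, -1, 0.5, -0.5), 2, 2,
                               dimnames = list(NULL, c("f1", "f2"))))
  fm1$standardized <- TRUE
  expect_equal(predict_zeta(fit1, fm1)[[1]][1], exp(-0.2))
})
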