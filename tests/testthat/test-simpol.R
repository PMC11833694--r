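test_that("configuration guards against probability overflow", {
  expect_error(simpol_config(100, zeta = rep(6, 100), time_slice = 1e-3),
               "probability")
  expect_error(simpol_config(100, alpha = 20000), "initiation")
  expect_silent(simpol_config(100, alpha = 1, seed = 1))
})

test_that("no initiation means no occupancy; seeds give determinism", {
  cfg <- simpol_config(200, n_cells = 20, alpha = 0, seed = 1)
  expect_equal(sum(simulate_occupancy(cfg)), 0)
  cfg2 <- simpol_config(200, n_cells = 50, alpha = 2, total_time = 2, seed = 42)
  expect_identical(simulate_occupancy(cfg2), simulate_occupancy(cfg2))
  cfg3 <- simpol_config(200, n_cells = 50, alpha = 2, total_time = 2, seed = 43)
  expect_false(identical(simulate_occupancy(cfg2), simulate_occupancy(cfg3)))
})

test_that("occupancy follows the steady-state 1/zeta law", {
  n <- 2000
  zeta <- rep(c(1, 0.5), each = n / 2)
  cfg <- simpol_config(n, n_cells = 400, alpha = 1, zeta = zeta, seed = 11)
  occ <- simulate_occupancy(cfg)
  # interior flat segments sit at alpha / (zeta_bar * zeta)
  left <- mean(occ[200:900])
  right <- mean(occ[1100:1900])
  expect_equal(left, 1 / 2000, tolerance = 0.1)
  expect_equal(right / left, 2, tolerance = 0.1)
  # regression of log occupancy on log zeta has slope -1
  sel <- c(200:900, 1100:1900)
  slope <- unname(coef(lm(log(occ[sel]) ~ log(zeta[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.05)
})

test_that("event-driven and slice samplers agree statistically", {
  zeta <- rep(c(1, 0.6), each = 150)
  agree <- sapply(1:3, function(s) {
    cfg <- simpol_config(300, n_cells = 800, alpha = 2, zeta = zeta,
                         total_time = 2, seed = 100 + s)
    oe <- simulate_occupancy(cfg, method = "event")
    os <- simulate_occupancy(cfg, method = "slice")
    mean(oe[30:290]) / mean(os[30:290])
  })
  # per-seed ratios fluctuate with shared initiation noise (~2-3%);
  # the mean over seeds must be near 1
  expect_equal(mean(agree), 1, tolerance = 0.04)
})

test_that("raising the initiation rate never decreases occupancy (collisions)", {
  cfg_lo <- simpol_config(300, n_cells = 600, alpha = 0.5, total_time = 4,
                          seed = 5)
  cfg_hi <- simpol_config(300, n_cells = 600, alpha = 5, total_time = 4,
                          seed = 5)
  o_lo <- simulate_occupancy(cfg_lo)
  o_hi <- simulate_occupancy(cfg_hi)
  expect_gt(mean(o_hi), mean(o_lo))
  expect_gt(min(o_hi[10:290] - o_lo[10:290]), -0.002)
})

test_that("read sampling hits the target depth with Poisson dispersion", {
  set.seed(1)
  occ <- rep(0.001, 10000)
  x <- sample_reads(occ, target_depth = 0.5)
  expect_equal(mean(x), 0.5, tolerance = 3 * sqrt(0.5 / 10000) / 0.5)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
  expect_equal(sample_reads(occ, target_depth = 0), integer(10000))
  expect_error(sample_reads(numeric(10), target_depth = 1), "all-zero")
  expect_error(sample_reads(c(-1, 1), target_depth = 1), "negative")
})

test_that("block-sampled covariates preserve the target correlations", {
  lib <- synthetic_block_library(n_blocks = 400, block_size = 100, seed = 2)
  Y <- sample_covariates(lib, 300000, seed = 3)
  R_target <- default_epigenomic_features()$correlation
  # block-level empirical correlation vs target
  Rb <- cor(Y[seq(1, nrow(Y), by = 100), ])
  expect_lt(max(abs(Rb - R_target)), 0.1)
  # single-block library tiles that block
  lib1 <- structure(list(values = matrix(1:6, 1, 6,
                                         dimnames = list(NULL, lib$names)),
                         block_size = 10L, names = lib$names),
                    class = "elr_block_library")
  Y1 <- sample_covariates(lib1, 25)
  expect_true(all(Y1[, 1] == 1) && all(Y1[, 6] == 6))
  # determinism
  expect_identical(sample_covariates(lib, 500, seed = 9),
                   sample_covariates(lib, 500, seed = 9))
})

test_that("make_zeta adds calibrated noise above a positive floor", {
  fm <- standardize(feature_matrix(matrix(rnorm(5000), ncol = 1)))
  z0 <- make_zeta(0.1, fm, noise_sd = 0)[[1]]
  expect_equal(z0, exp(0.1 * fm$values[[1]][, 1]))
  expect_equal(make_zeta(0, fm, noise_sd = 0)[[1]], rep(1, 5000))
  z <- make_zeta(0.1, fm, noise_sd = 0.1, seed = 4)[[1]]
  expect_equal(sd(z - z0), 0.1, tolerance = 0.05)
  expect_true(all(z >= 1e-3))
})
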