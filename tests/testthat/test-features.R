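test_that("k-mer indicators align with the active site", {
  # even k: 1-based position k/2 of the k-mer sits on the site
  expect_equal(which(kmer_indicators("GCAT", "CA") == 1), 2L)
  # odd k: middle base on the site
  expect_equal(which(kmer_indicators("GCAT", "GCA") == 1), 2L)
  # windows overrunning the TU ends give 0
  expect_equal(which(kmer_indicators("TTTTT", "TTT") == 1), c(2L, 3L, 4L))
  # N in the sequence kills any window containing it
  expect_equal(sum(kmer_indicators("ACNGT", "CG")), 0)
  expect_equal(which(kmer_indicators("ACNGA", "GA") == 1), 4L)
  expect_error(kmer_indicators("ACGT", "CX"), "A/C/G/T")
})

test_that("k-mer shift translates the indicator pattern", {
  s <- "GCATGCATGCAT"
  base <- which(kmer_indicators(s, "CA") == 1)
  shifted <- which(kmer_indicators(s, "CA", shift = -5L) == 1)
  expect_equal(shifted, base[base + 5 <= nchar(s)] + 5)
})

test_that("1-mer indicators partition non-N sites", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  m <- kmer_indicators(s, c("A", "C", "G", "T"))
  expect_true(all(rowSums(m) == 1))
})

test_that("grouped k-mer features match dense indicators exactly", {
  seqs <- random_seqs(3, 150, seed = 11)
  for (kk in list(1L, 2L, "k<=5")) {
    kf <- kmer_features(seqs, kmers = kk)
    fmd <- as_dense_features(kf)
    for (j in seq_along(seqs)) {
      dense <- kmer_indicators(seqs[[j]], kf$names)
      expect_equal(unname(fmd$values[[j]]),
                   unname(matrix(as.numeric(dense), nrow(dense))))
    }
  }
})

test_that("filters normalize, preserve constants and pass impulses", {
  f <- gaussian_filter(r = 2, sigma = 1)
  x <- c(0, 0, 0, 1, 0, 0, 0)
  y <- apply_filter(x, f)
  expect_equal(sum(y), 1)           # interior impulse: mass preserved
  expect_equal(which.max(y), 4L)
  expect_equal(apply_filter(rep(3.5, 20), f)[5:16], rep(3.5, 12))
  # generalized identity
  g <- generalized_filter(c(0, 0, 1, 0, 0))
  expect_equal(apply_filter(x, g), x)
  # delta shifts the kernel
  gd <- generalized_filter(c(0, 0, 1, 0, 0), delta = 2L)
  expect_equal(apply_filter(x, gd), c(0, 1, 0, 0, 0, 0, 0))
  expect_error(generalized_filter(c(0, 0, 0)), "all-zero")
  expect_error(generalized_filter(c(1, 1)), "odd")
})

test_that("generalized filters are estimated from metaplot excursions", {
  expect_error(estimate_generalized_filter(rep(1, 11), r = 5), "flat")
  prof <- rep(1, 11); prof[9] <- 3
  fs <- estimate_generalized_filter(prof, r = 5)
  expect_equal(which(fs$weights > 0), 9L)
  # scale invariance after normalization
  f1 <- estimate_generalized_filter(prof, r = 5)
  f10 <- estimate_generalized_filter(prof * 10, r = 5)
  x <- rnorm(30)
  expect_equal(apply_filter(x, f1), apply_filter(x, f10))
  expect_error(estimate_generalized_filter(prof[1:5], r = 5), "shorter")
})

test_that("standardization: stats, zero-fill, closed forms, idempotence", {
  # two defined methylation-like values standardize to +/-1, rest exactly 0
  v <- matrix(0, 10, 1)
  v[c(3, 7), 1] <- c(0.2, 0.8)
  def <- matrix(FALSE, 10, 1); def[c(3, 7), 1] <- TRUE
  fs <- standardize(feature_matrix(v, names = "meth", defined = def))
  expect_equal(fs$values[[1]][c(3, 7), 1], c(-1, 1))
  expect_equal(fs$values[[1]][-c(3, 7), 1], rep(0, 8))

  # Bernoulli closed form (population sd): ones -> sqrt((1-q)/q)
  q <- 0.2
  x <- c(rep(1, 20), rep(0, 80))
  fs2 <- standardize(feature_matrix(matrix(x, ncol = 1)))
  expect_equal(sort(unique(fs2$values[[1]][, 1])),
               c(-sqrt(q / (1 - q)), sqrt((1 - q) / q)))
  expect_equal(mean(fs2$values[[1]]), 0, tolerance = 1e-12)
  expect_equal(mean(fs2$values[[1]]^2), 1, tolerance = 1e-12)

  # constant features are dropped with a warning
  expect_warning(
    fs3 <- standardize(feature_matrix(cbind(one = rep(1, 5), ok = rnorm(5)))),
    "constant")
  expect_identical(fs3$names, "ok")

  # idempotent on its own output
  fs4 <- standardize(fs2)
  expect_equal(fs4$values[[1]], fs2$values[[1]], tolerance = 1e-10)
})

test_that("grouped standardization matches dense and supports train stats", {
  seqs <- random_seqs(4, 200, seed = 5)
  kf <- standardize(kmer_features(seqs, 2L))
  fmd <- standardize(as_dense_features(kmer_features(seqs, 2L)))
  common <- intersect(kf$names, fmd$names)
  expect_equal(kf$center[common], fmd$center[common], tolerance = 1e-12)
  expect_equal(kf$scale[common], fmd$scale[common], tolerance = 1e-12)
  # training-only statistics
  kf_tr <- standardize(kmer_features(seqs, 2L), stats_from = 1:2)
  fmd_tr <- standardize(as_dense_features(kmer_features(seqs, 2L)),
                        stats_from = 1:2)
  common <- intersect(kf_tr$names, fmd_tr$names)
  expect_equal(kf_tr$center[common], fmd_tr$center[common], tolerance = 1e-12)
})
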