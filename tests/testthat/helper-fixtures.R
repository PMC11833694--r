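# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

make_tus <- function(M, n, lambda = 1, strand = "+", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(M), function(j)
    transcription_unit(paste0("g", j), "chrS", strand,
                       (j - 1) * (n + 100), (j - 1) * (n + 100) + n,
                       counts = rpois(n, lambda)))
}

random_seqs <- function(M, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(M), function(j)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Gaussian covariates + model-generated Poisson counts (no SimPol), for fast
# GLM parameter-recovery checks
glm_toy <- function(M = 4, n = 800, kappa = c(-0.2, 0.1, 0.05),
                    chi = NULL, seed = 1) {
  set.seed(seed)
  F <- length(kappa)
  fm <- standardize(feature_matrix(lapply(seq_len(M), function(j)
    matrix(rnorm(n * F), n, F))))
  zeta <- make_zeta(kappa, fm, noise_sd = 0)
  if (is.null(chi)) chi <- runif(M, 0.5, 2)
  tus <- lapply(seq_len(M), function(j)
    transcription_unit(paste0("g", j), "chrS", "+", (j - 1) * 2 * n,
                       (j - 1) * 2 * n + n,
                       counts = rpois(n, chi[j] / zeta[[j]])))
  list(tus = tus, features = fm, kappa = kappa, chi = chi, zeta = zeta)
}

write_temp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent 1-D maximizer: golden-section search followed by one parabolic
# refinement through the final bracket, which pushes the accuracy past the
# sqrt(machine-eps) plateau of pure comparison-based search.
golden_max <- function(f, lo, hi, iter = 80) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (k in seq_len(iter)) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
    if (b - a < 1e-6 * max(1, abs(a))) break
  }
  m <- (a + b) / 2
  h <- 3e-5 * max(1, abs(m))
  fm <- f(m); fp <- f(m + h); fn <- f(m - h)
  denom <- fp - 2 * fm + fn
  if (denom < 0) m + h * (fn - fp) / (2 * denom) else m
}
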