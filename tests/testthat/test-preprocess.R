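test_that("gene bodies are trimmed +2250/-250 and short bodies dropped", {
  gb <- define_gene_body(0, 10000, "+")
  expect_equal(gb, list(start = 2250, end = 9750))
  expect_null(define_gene_body(0, 8000, "+"))   # 5750 < 6000
  # minus strand mirrored
  gbm <- define_gene_body(10000, 0, "-")
  expect_equal(gbm, list(start = 250, end = 7750))
  expect_error(define_gene_body(10, 5, "+"), "tss < tts")
  expect_error(define_gene_body(5, 10, "-"), "tss > tts")
})

test_that("internal TSS masking follows the cap-count rule and merges windows", {
  tu <- transcription_unit("g", "c", "+", 0, 8000)
  mid <- 4000
  caps <- data.frame(chrom = "c", pos = mid, count = 11)
  m <- mask_internal_signals(tu, cap_sites = caps)
  expect_equal(sum(!m$mask), 2000)
  expect_false(any(m$mask[(mid - 1000 + 1):(mid + 1000)]))
  # count == threshold is not masked (strict inequality)
  caps10 <- data.frame(chrom = "c", pos = mid, count = 10)
  expect_true(all(mask_internal_signals(tu, cap_sites = caps10)$mask))
  # overlapping peak + cap windows merge; masks only remove sites
  peaks <- interval_set("c", 4500, 5500)
  m2 <- mask_internal_signals(tu, peak_intervals = peaks, cap_sites = caps)
  expect_equal(sum(!m2$mask), length(union(3001:5000, 4501:5500)))
  expect_true(all(m2$mask | !m$mask | !mask_internal_signals(tu, peak_intervals = peaks)$mask))
  # empty annotations leave the mask untouched
  expect_true(all(mask_internal_signals(tu)$mask))
  # minus strand: genomic window maps through the flip
  tum <- transcription_unit("g", "c", "-", 0, 8000)
  mm <- mask_internal_signals(tum, cap_sites = caps)
  expect_equal(sum(!mm$mask), 2000)
})

test_that("LOESS flattening removes a synthetic U-shaped profile", {
  set.seed(21)
  n_genes <- 60
  shape <- function(rel) 1 + 0.25 * (2 * rel - 1)^2 - 0.25 / 3  # mean ~1, dips mid
  tus <- lapply(seq_len(n_genes), function(j) {
    n <- sample(6000:9000, 1)
    rel <- (seq_len(n) - 0.5) / n
    transcription_unit(paste0("g", j), "c", "+", 0, n,
                       counts = rpois(n, 8 * shape(rel)))
  })
  fl <- loess_flatten(tus, n_bins = 100)
  # adjusted cross-gene mean profile is flat within 2%
  prof <- rowMeans(sapply(fl$tus, function(tu) {
    n <- tu_length(tu)
    b <- ceiling(seq_len(n) / n * 100)
    as.numeric(tapply(tu$counts, b, mean)) / mean(tu$counts)
  }))
  expect_lt(max(abs(prof / mean(prof) - 1)), 0.02)
  # per-gene totals conserved within 5%
  tot_before <- vapply(tus, function(t) sum(t$counts), 0)
  tot_after <- vapply(fl$tus, function(t) sum(t$counts), 0)
  expect_lt(max(abs(tot_after / tot_before - 1)), 0.05)
  # local contrasts preserved: counts 100 nt apart keep their ratio
  tu1 <- tus[[1]]; ft1 <- fl$tus[[1]]
  i <- which(tu1$counts[1:6000] > 0)
  i <- i[i + 100 <= tu_length(tu1) & tu1$counts[i + 100] > 0][1:50]
  r_before <- tu1$counts[i] / tu1$counts[i + 100]
  r_after <- ft1$counts[i] / ft1$counts[i + 100]
  expect_lt(median(abs(r_after / r_before - 1)), 0.01)
  # zero-median genes are excluded with a warning
  tus2 <- c(tus[1:5], list(transcription_unit("z", "c", "+", 0, 6000)))
  expect_warning(fl2 <- loess_flatten(tus2, n_bins = 100), "zero median")
  expect_identical(fl2$excluded, "z")
})

test_that("already-flat profiles are left nearly unchanged", {
  set.seed(22)
  tus <- lapply(1:10, function(j)
    transcription_unit(paste0("g", j), "c", "+", 0, 6000,
                       counts = rpois(6000, 4)))
  fl <- loess_flatten(tus, n_bins = 100)
  expect_lt(max(abs(fl$curve - 1)), 0.03)
})

test_that("pausing windows rank by summed counts with 5'-most tie-break", {
  counts <- numeric(2000)
  counts[501:520] <- 50  # spike in window 3 (401-600)
  tu <- transcription_unit("g", "c", "+", 0, 2000, counts = counts)
  pw <- pausing_locations(tu, window = 200, top_k = 5)
  expect_equal(pw$start[1], 401)
  expect_equal(pw$sum[1], 1000)
  # uniform counts: first five windows by tie-break
  tu2 <- transcription_unit("g", "c", "+", 0, 2000, counts = rep(1, 2000))
  pw2 <- pausing_locations(tu2, window = 200, top_k = 5)
  expect_equal(pw2$start, c(1, 201, 401, 601, 801))
  # short body: fewer windows with a warning
  expect_warning(pw3 <- pausing_locations(rep(1, 450), window = 200, top_k = 5),
                 "window")
  expect_equal(nrow(pw3), 2)
})

test_that("coverage ratio arithmetic and invariance to gene rescaling", {
  tu <- transcription_unit("g", "c", "+", 0, 4, counts = c(2, 2, 2, 2))
  expect_equal(coverage_ratio(tu, c(TRUE, TRUE, FALSE, FALSE)), 1)
  tu2 <- transcription_unit("g", "c", "+", 0, 4, counts = c(4, 4, 1, 1))
  expect_equal(coverage_ratio(tu2, c(TRUE, TRUE, FALSE, FALSE)), 4)
  # rescaling one gene's counts changes nothing (relative depths)
  tu3 <- tu2; tu3$counts <- tu3$counts * 10
  expect_equal(coverage_ratio(list(tu2, tu3),
                              list(c(TRUE, TRUE, FALSE, FALSE),
                                   c(TRUE, TRUE, FALSE, FALSE))), 4)
  expect_error(coverage_ratio(tu, rep(TRUE, 4)), "uncovered")
  expect_error(coverage_ratio(tu, rep(FALSE, 4)), "covered")
})

test_that("metaplots average relative depth around anchors", {
  tu <- transcription_unit("g", "c", "+", 0, 100, counts = rep(2, 100))
  mp <- metaplot(tu, list(50), radius = 5)
  expect_equal(unname(mp), rep(1, 11))
  # single anchor equals that window's relative depths
  counts <- rpois(100, 3) + 1
  tu2 <- transcription_unit("g", "c", "+", 0, 100, counts = counts)
  mp2 <- metaplot(tu2, list(40), radius = 3)
  expect_equal(unname(mp2), counts[37:43] / mean(counts))
  expect_error(metaplot(tu, list(integer()), radius = 5), "anchors")
  # metaplot output feeds the generalized-filter estimator
  prof <- rep(1, 21); prof[15] <- 2
  expect_s3_class(estimate_generalized_filter(prof, r = 10), "elr_filter")
})
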