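# Preprocessing of raw per-nucleotide counts into model-ready TUs, plus the
# non-model validation statistics (coverage ratios, metaplots, pausing
# windows).

#' Define a trimmed gene body
#'
#' The analyzed gene body runs from 2250 bp downstream of the (refined) TSS
#' -- far enough to exclude promoter-proximal pause peaks -- to 250 bp
#' upstream of the annotated TTS. Bodies shorter than 6 kb are omitted
#' (returns NULL).
#'
#' @param tss,tts 0-based genomic positions of the transcription start and
#'   termination sites. For minus-strand genes `tss > tts`.
#' @param strand `"+"` or `"-"`.
#' @param tss_trim,tts_trim trim distances in nucleotides.
#' @param min_length minimum body length kept.
#' @return A list with `start`, `end` (0-based half-open) or NULL if the
#'   trimmed body is shorter than `min_length`.
#' @export
define_gene_body <- function(tss, tts, strand, tss_trim = 2250,
                             tts_trim = 250, min_length = 6000) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") {
    if (!(tss < tts)) stop("define_gene_body: need tss < tts on +")
    start <- tss + tss_trim; end <- tts - tts_trim
  } else {
    if (!(tss > tts)) stop("define_gene_body: need tss > tts on -")
    start <- tts + tts_trim; end <- tss - tss_trim
  }
  if (end - start < min_length) return(NULL)
  list(start = start, end = end)
}

#' Mask internal transcription-initiation signals
#'
#' Read density around intragenic transcription start sites reflects
#' initiation, not elongation, so such regions are removed from all model
#' sums: sites inside predicted regulatory-element peaks and sites within a
#' 2-kb window centered on any cap-site (GRO-cap/PRO-cap style) peak with
#' read count strictly greater than the threshold are set to `FALSE` in the
#' TU mask. Masks only ever remove sites; overlapping windows merge.
#'
#' @param tu an `elr_tu`.
#' @param peak_intervals optional [interval_set()] of peak calls (genomic).
#' @param cap_sites optional data frame with columns `chrom`, `pos` (0-based
#'   genomic) and `count`.
#' @param cap_count_threshold mask cap sites with `count >` this value.
#' @param cap_radius half-width of the masked window around a cap site.
#' @return The TU with an updated mask.
#' @export
mask_internal_signals <- function(tu, peak_intervals = NULL,
                                  cap_sites = NULL,
                                  cap_count_threshold = 10,
                                  cap_radius = 1000) {
  mask <- tu$mask
  drop <- rep(FALSE, tu_length(tu))
  if (!is.null(peak_intervals) && nrow(peak_intervals)) {
    ov <- overlap_intervals(peak_intervals, tu$chrom, tu$start, tu$end)
    for (k in seq_len(nrow(ov))) {
      pos <- max(ov$start[k], tu$start):(min(ov$end[k], tu$end) - 1)
      drop[tu_index(tu, pos)] <- TRUE
    }
  }
  if (!is.null(cap_sites) && nrow(cap_sites)) {
    sel <- cap_sites$chrom == tu$chrom & cap_sites$count > cap_count_threshold
    for (p in cap_sites$pos[sel]) {
      lo <- max(p - cap_radius, tu$start)
      hi <- min(p + cap_radius, tu$end)
      if (hi > lo) drop[tu_index(tu, lo:(hi - 1))] <- TRUE
    }
  }
  tu$mask <- mask & !drop
  tu
}

#' Remove the shared U-shaped gene-body profile by LOESS adjustment
#'
#' Gene-body read depth shows a shared U-shaped trend along the body (higher
#' near both ends). To remove it, gene positions are mapped to a common
#' relative scale of `n_bins` bins, binned counts are normalized by each
#' gene's median binned value, the cross-gene mean profile is smoothed with
#' LOESS and rescaled to average height 1, and every raw count is divided by
#' the curve height at its relative position. The adjusted cross-gene
#' profile is flat on average, while within-gene local contrasts are
#' essentially untouched (the curve is smooth on the scale of hundreds of
#' nucleotides).
#'
#' @param tus list of TUs (>= 2 with positive median binned counts; genes
#'   with a zero median are excluded with a warning).
#' @param n_bins number of relative-position bins.
#' @param span LOESS span.
#' @param curve_floor lower bound applied to the curve before dividing, to
#'   avoid blow-ups at extreme ends.
#' @return A list with `tus` (adjusted counts, original order minus
#'   exclusions), `curve` (height per bin), `excluded` (ids).
#' @export
loess_flatten <- function(tus, n_bins = 1000, span = 0.3,
                          curve_floor = 0.1) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  binned <- lapply(tus, function(tu) {
    n <- tu_length(tu)
    b <- ceiling(seq_len(n) / n * n_bins)
    as.numeric(tapply(tu$counts, b, mean))
  })
  med <- vapply(binned, median, 0)
  bad <- med <= 0
  if (any(bad))
    warning("loess_flatten: excluding ", sum(bad),
            " gene(s) with zero median binned counts")
  if (sum(!bad) < 2) stop("loess_flatten: need >= 2 usable genes")
  prof <- rowMeans(do.call(cbind, Map(`/`, binned[!bad], med[!bad])))
  rel <- (seq_len(n_bins) - 0.5) / n_bins
  lo <- loess(prof ~ rel, span = span, degree = 2)
  curve <- predict(lo, rel)
  curve <- curve / mean(curve)
  curve <- pmax(curve, curve_floor)
  adjusted <- lapply(tus[!bad], function(tu) {
    n <- tu_length(tu)
    b <- ceiling(seq_len(n) / n * n_bins)
    tu$counts <- tu$counts / curve[b]
    tu
  })
  list(tus = adjusted, curve = curve,
       excluded = vapply(tus[bad], `[[`, "", "id"))
}

#' Putative pausing locations within a gene body
#'
#' The body is partitioned into non-overlapping windows tiled from the 5'
#' end (a final partial window is dropped), read counts are summed within
#' each window, and the `top_k` windows by summed count are returned as
#' putative pausing locations. Ties are broken in favor of the 5'-most
#' window.
#'
#' @param tu an `elr_tu` (or a plain counts vector).
#' @param window window size in nucleotides.
#' @param top_k number of windows to return.
#' @return Data frame with 1-based TU-relative `start`, `end`, the window
#'   `sum` and `rank`; fewer than `top_k` rows (with a warning) for short
#'   bodies.
#' @export
pausing_locations <- function(tu, window = 200, top_k = 5) {
  counts <- if (inherits(tu, "elr_tu")) tu$counts else tu
  nwin <- floor(length(counts) / window)
  if (nwin < 1) stop("pausing_locations: body shorter than one window")
  if (nwin < top_k)
    warning("pausing_locations: only ", nwin, " full window(s)")
  sums <- vapply(seq_len(nwin), function(w)
    sum(counts[((w - 1) * window + 1):(w * window)]), 0)
  ord <- order(-sums, seq_len(nwin))
  sel <- ord[seq_len(min(top_k, nwin))]
  data.frame(start = (sel - 1) * window + 1, end = sel * window,
             sum = sums[sel], rank = seq_along(sel))
}

#' Relative read-depth ratio between covered and uncovered sites
#'
#' For each gene the relative read depth is the count divided by the gene's
#' mean count (removing differences in initiation and average elongation
#' rate); the statistic is the pooled mean relative depth over sites covered
#' by a feature divided by the pooled mean over uncovered sites. A ratio > 1
#' indicates increased read depth -- i.e. slower elongation -- at the
#' feature.
#'
#' @param tus list of TUs.
#' @param feature_mask list of logical vectors (TRUE = covered), parallel to
#'   `tus`.
#' @return The ratio (scalar).
#' @export
coverage_ratio <- function(tus, feature_mask) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  if (!is.list(feature_mask)) feature_mask <- list(feature_mask)
  stopifnot(length(tus) == length(feature_mask))
  cov <- unc <- numeric()
  for (j in seq_along(tus)) {
    m <- mean(tus[[j]]$counts)
    if (m == 0) next
    rel <- tus[[j]]$counts / m
    cov <- c(cov, rel[feature_mask[[j]]])
    unc <- c(unc, rel[!feature_mask[[j]]])
  }
  if (!length(cov)) stop("coverage_ratio: no covered sites")
  if (!length(unc)) stop("coverage_ratio: no uncovered sites")
  mean(cov) / mean(unc)
}

#' Metaplot of relative read depth around feature anchors
#'
#' Averages the per-gene relative read depth (counts over gene mean) at each
#' offset in `[-radius, radius]` around the given anchor positions,
#' strand-oriented (anchors and offsets are in transcription coordinates).
#' The resulting profile feeds [estimate_generalized_filter()].
#'
#' @param tus list of TUs.
#' @param anchors list (parallel to `tus`) of 1-based anchor positions
#'   within each TU.
#' @param radius window half-width in nucleotides.
#' @return Numeric vector of length `2*radius + 1`, names giving offsets.
#' @export
metaplot <- function(tus, anchors, radius) {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  if (!is.list(anchors)) anchors <- list(anchors)
  stopifnot(length(tus) == length(anchors))
  if (sum(lengths(anchors)) == 0) stop("metaplot: no anchors")
  offs <- -radius:radius
  acc <- cnt <- numeric(length(offs))
  for (j in seq_along(tus)) {
    m <- mean(tus[[j]]$counts)
    if (m == 0) next
    rel <- tus[[j]]$counts / m
    n <- length(rel)
    for (a in anchors[[j]]) {
      pos <- a + offs
      ok <- pos >= 1 & pos <= n
      acc[ok] <- acc[ok] + rel[pos[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
  }
  stats::setNames(acc / pmax(cnt, 1), offs)
}
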