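# YAML-driven covariate assembly, used by the command-line interface.
#
# A feature configuration is a YAML list under `features:`, one entry per
# covariate:
#
#   features:
#     - name: H3K36me3
#       track: h3k36me3.bedgraph        # per-base values, or
#       # bed: ctcf_peaks.bed           # intervals -> 0/1 indicator
#       filter: {kind: gaussian, r: 400, sigma: 100, delta: 0}
#       defined: all                    # or "nonzero"
#     - name: methylation
#       track: wgbs.bedgraph
#       defined: nonzero                # defined at annotated sites only
#
# Filters are applied before standardization; `defined: nonzero` marks raw
# zeros as undefined so standardization zero-fills them (the DNA-methylation
# convention).

#' Read a YAML feature configuration
#'
#' @param path YAML file with a top-level `features:` list; see the package
#'   source for the accepted fields.
#' @return The parsed configuration (a list).
#' @export
read_feature_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_feature_config requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$features)) stop("feature config: missing 'features:' list")
  cfg
}

#' Build a covariate matrix from a feature configuration
#'
#' Reads each configured track (bedGraph) or interval file (BED indicator),
#' applies the configured smoothing filter, records the defined-mask, and
#' returns an unstandardized [feature_matrix()] over the given TUs.
#'
#' @param config a [read_feature_config()] result (or equivalent list).
#' @param tus list of TUs.
#' @param base_dir directory for relative paths in the config.
#' @return An [feature_matrix()].
#' @export
build_feature_matrix <- function(config, tus, base_dir = ".") {
  if (inherits(tus, "elr_tu")) tus <- list(tus)
  feats <- config$features
  nm <- vapply(feats, function(f) f$name, "")
  vals <- lapply(tus, function(tu) matrix(0, tu_length(tu), length(feats),
                                          dimnames = list(NULL, nm)))
  defs <- lapply(tus, function(tu) matrix(TRUE, tu_length(tu), length(feats)))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    raw <- if (!is.null(f$track)) {
      read_counts_track(file.path(base_dir, f$track), tus, raw = TRUE)
    } else if (!is.null(f$bed)) {
      iv <- read_bed(file.path(base_dir, f$bed))
      lapply(tus, function(tu) {
        v <- numeric(tu_length(tu))
        ov <- overlap_intervals(iv, tu$chrom, tu$start, tu$end)
        for (r in seq_len(nrow(ov))) {
          pos <- max(ov$start[r], tu$start):(min(ov$end[r], tu$end) - 1)
          v[tu_index(tu, pos)] <- 1
        }
        v
      })
    } else stop("feature '", f$name, "': needs a 'track' or 'bed' source")
    if (identical(f$defined, "nonzero"))
      for (j in seq_along(tus)) defs[[j]][, k] <- raw[[j]] != 0
    if (!is.null(f$filter)) {
      fs <- f$filter
      spec <- if (identical(fs$kind, "gaussian"))
        gaussian_filter(fs$r, fs$sigma, fs$delta %||% 0L)
      else generalized_filter(unlist(fs$weights), fs$delta %||% 0L)
      raw <- lapply(raw, apply_filter, spec = spec)
    }
    for (j in seq_along(tus)) vals[[j]][, k] <- raw[[j]]
  }
  feature_matrix(vals, names = nm, defined = defs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
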