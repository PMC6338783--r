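#' Depth-normalize a coverage matrix
#'
#' Scales each sample column to counts-per-million then applies a
#' log2(x + 1) transform, making coverage-style signal comparable across
#' samples of different sequencing depth.
#'
#' @param raw Numeric matrix, regions x samples; all column sums must be
#'   positive.
#' @return Matrix of the same shape on the log2 CPM scale.
#' @export
normalize_coverage <- function(raw) {
  raw <- as.matrix(raw)
  cs <- colSums(raw)
  if (any(cs <= 0)) {
    bad <- colnames(raw)[which(cs <= 0)[1L]]
    if (is.null(bad)) bad <- which(cs <= 0)[1L]
    stop("zero-sum coverage column for sample: ", bad)
  }
  log2(sweep(raw, 2L, cs, "/") * 1e6 + 1)
}

#' Call differentially methylated regions from paired coverage signal
#'
#' Per region, a paired two-sided Wilcoxon signed-rank test compares
#' normalized tumor vs matched non-tumor signal across patients; p-values
#' are Bonferroni-adjusted over the number of testable regions and regions
#' with adjusted p below `alpha` are reported with a direction (hypo when
#' the mean paired tumor - non-tumor difference is negative). Regions whose
#' paired differences are all exactly zero are untestable and excluded from
#' the Bonferroni family.
#'
#' @param signal Normalized regions x samples matrix (see
#'   [normalize_coverage()]); rownames identify regions.
#' @param pairs Data.frame with columns `tumor` and `non_tumor` naming
#'   matched sample columns of `signal`.
#' @param alpha Bonferroni-adjusted significance cutoff in (0, 1],
#'   default 0.1.
#' @return Data.frame with columns `region`, `effect` (mean paired
#'   difference), `p_value`, `p_adjusted`, `direction`; attribute
#'   `n_tested` records the Bonferroni family size.
#' @export
call_dmrs <- function(signal, pairs, alpha = 0.1) {
  signal <- as.matrix(signal)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  stopifnot(all(c("tumor", "non_tumor") %in% names(pairs)))
  missing <- setdiff(c(pairs$tumor, pairs$non_tumor), colnames(signal))
  if (length(missing)) {
    stop("unpaired/unknown sample(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(pairs) < 6L) stop("need at least 6 tumor/non-tumor pairs")
  regions <- rownames(signal)
  if (is.null(regions)) regions <- paste0("region_", seq_len(nrow(signal)))
  diffs <- signal[, pairs$tumor, drop = FALSE] -
    signal[, pairs$non_tumor, drop = FALSE]
  testable <- rowSums(diffs != 0) > 0
  n_tested <- sum(testable)
  res <- data.frame(region = regions[testable],
                    effect = rowMeans(diffs[testable, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  res$p_value <- if (n_tested) {
    apply(diffs[testable, , drop = FALSE], 1L, function(d) {
      wilcoxon_signed_rank(d)$p_value
    })
  } else numeric(0)
  res$p_adjusted <- pmin(1, res$p_value * n_tested)
  res <- res[res$p_adjusted < alpha, , drop = FALSE]
  res$direction <- ifelse(res$effect < 0, "hypo", "hyper")
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  res
}

#' Split DMR calls by direction
#'
#' @param dmrs Data.frame from [call_dmrs()] (needs a `direction` column).
#' @return List with elements `hypo` and `hyper`.
#' @export
split_by_direction <- function(dmrs) {
  list(hypo = dmrs[dmrs$direction == "hypo", , drop = FALSE],
       hyper = dmrs[dmrs$direction == "hyper", , drop = FALSE])
}
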