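#' Classify regions as active enhancers from histone-mark signal
#'
#' An active enhancer carries substantial H3K27ac enrichment over local
#' background, a high H3K4me1 to H3K4me3 ratio and low H3K27me3:
#' H3K27ac/background >= `k27ac_fold_min` AND
#' (H3K4me1 + eps)/(H3K4me3 + eps) >= `me1_me3_ratio_min` AND
#' H3K27me3/background < `k27me3_fold_max`. Thresholds are calibrated on
#' the bundled generator and fully configurable.
#'
#' @param rs Data.frame with numeric columns `H3K27ac`, `H3K4me1`,
#'   `H3K4me3`, `H3K27me3` and `background` (> 0).
#' @param k27ac_fold_min,me1_me3_ratio_min,k27me3_fold_max Thresholds
#'   (defaults 2.0, 2.0, 1.5).
#' @param eps Pseudocount stabilizing the me1/me3 ratio (default 1).
#' @return Logical vector, one per row.
#' @export
classify_active_enhancer <- function(rs, k27ac_fold_min = 2,
                                     me1_me3_ratio_min = 2,
                                     k27me3_fold_max = 1.5, eps = 1) {
  need <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3", "background")
  miss <- setdiff(need, names(rs))
  if (length(miss)) stop("missing mark column(s): ",
                         paste(miss, collapse = ", "))
  if (any(rs$background <= 0)) stop("background must be > 0")
  (rs$H3K27ac / rs$background >= k27ac_fold_min) &
    ((rs$H3K4me1 + eps) / (rs$H3K4me3 + eps) >= me1_me3_ratio_min) &
    (rs$H3K27me3 / rs$background < k27me3_fold_max)
}

#' Partition regions into TSS-proximal promoters and TSS-distal enhancers
#'
#' A region is promoter-class when its midpoint lies within `window` bp
#' (inclusive) of any transcription start site, else enhancer-class.
#'
#' @param regions `GRanges` of regions.
#' @param tss Data.frame with columns `gene`, `chrom`, `pos`.
#' @param window Promoter window in bp (default 2000).
#' @return Character vector of `"promoter"` / `"enhancer"`.
#' @export
assign_region_class <- function(regions, tss, window = 2000) {
  stopifnot(nrow(tss) > 0)
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2
  chr <- as.character(GenomicRanges::seqnames(regions))
  vapply(seq_along(regions), function(i) {
    pos <- tss$pos[tss$chrom == chr[i]]
    if (length(pos) && min(abs(pos - mid[i])) <= window) "promoter"
    else "enhancer"
  }, "")
}

#' Classify per-region signal change between conditions
#'
#' The perturbed/baseline ratio (after adding pseudocount `eps` to both) is
#' classified as `"loss"` when strictly below `loss_below` (default 1/2),
#' `"gain"` when strictly above `gain_above` (default 2), else `"stable"`;
#' ratios exactly at a threshold are stable.
#'
#' @param baseline,perturbed Non-negative signal vectors.
#' @param loss_below,gain_above Ratio cutoffs.
#' @param eps Pseudocount (default 1).
#' @return Character vector of `"loss"`, `"gain"`, `"stable"`.
#' @export
classify_signal_change <- function(baseline, perturbed, loss_below = 0.5,
                                   gain_above = 2, eps = 1) {
  if (any(baseline < 0) || any(perturbed < 0)) {
    stop("signals must be non-negative")
  }
  ratio <- (perturbed + eps) / (baseline + eps)
  ifelse(ratio < loss_below, "loss",
         ifelse(ratio > gain_above, "gain", "stable"))
}

#' Chi-square test of a 2x2 table with Yates continuity correction
#'
#' For a 2x2 table [[a, b], [c, d]] with margins m1, m2, n1, n2 and total
#' N, the statistic is N * (|ad - bc| - N/2)^2 / (m1 m2 n1 n2), clamped to
#' 0 when |ad - bc| <= N/2; p from the upper tail of chi-square with 1 df.
#'
#' @param table A 2x2 numeric matrix of non-negative counts with positive
#'   margins.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n1 <- a + b; n2 <- c_ + d; m1 <- a + c_; m2 <- b + d
  if (any(c(n1, n2, m1, m2) == 0)) stop("zero margin in 2x2 table")
  N <- a + b + c_ + d
  num <- abs(a * d - b * c_) - N / 2
  stat <- if (num <= 0) 0 else N * num^2 / (m1 * m2 * n1 * n2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Call super-enhancers by rank-signal curve geometry
#'
#' ROSE-style procedure: promoter-proximal peaks (midpoint within
#' `tss_exclusion_bp` of a TSS) are dropped; remaining peaks within
#' `stitch_bp` of each other are stitched into single regions;
#' background-subtracted signal (floored at 0) is summed per stitched
#' region; regions are ranked by total signal ascending and both rank and
#' signal are rescaled to [0, 1]. The cutoff is the first point, scanning
#' from the low-signal end, where the discrete slope of the scaled curve
#' exceeds 1 (the slope-1 tangent of the hockey stick); regions past it are
#' super-enhancers.
#'
#' @param peaks Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `signal` and optionally `background` (default 0).
#' @param stitch_bp Maximum gap stitched across (default 12500).
#' @param tss_exclusion_bp Promoter-proximity exclusion window
#'   (default 2000).
#' @param tss Optional TSS data.frame (`gene`, `chrom`, `pos`); when NULL
#'   no exclusion is applied.
#' @return Data.frame of stitched regions with `chrom`, `start`, `end`,
#'   `n_constituents`, `total_signal`, `rank`, `is_super`, ranked
#'   ascending by signal.
#' @export
call_super_enhancers <- function(peaks, stitch_bp = 12500L,
                                 tss_exclusion_bp = 2000L, tss = NULL) {
  stopifnot(all(c("chrom", "start", "end", "signal") %in% names(peaks)))
  bg <- if ("background" %in% names(peaks)) peaks$background else 0
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  gr$signal <- pmax(peaks$signal - bg, 0)
  if (!is.null(tss)) {
    cls <- assign_region_class(gr, tss, window = tss_exclusion_bp)
    gr <- gr[cls == "enhancer"]
  }
  if (length(gr) == 0L) stop("no peaks left after TSS exclusion")
  stitched <- GenomicRanges::reduce(gr, min.gapwidth = stitch_bp,
                                    ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, stitched, ignore.strand = TRUE)
  tot <- tapply(gr$signal[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  ncon <- tapply(S4Vectors::queryHits(hits),
                 S4Vectors::subjectHits(hits), length)
  n <- length(stitched)
  if (n < 3L) stop("fewer than 3 stitched regions; rank curve undefined")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(stitched)),
                   start = GenomicRanges::start(stitched) - 1L,
                   end = GenomicRanges::end(stitched),
                   n_constituents = as.integer(ncon[as.character(1:n)]),
                   total_signal = as.numeric(tot[as.character(1:n)]),
                   stringsAsFactors = FALSE)
  ord <- order(df$total_signal, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(n)
  rng <- range(df$total_signal)
  if (diff(rng) == 0) {
    df$is_super <- FALSE
  } else {
    x <- (df$rank - 1) / (n - 1)
    y <- (df$total_signal - rng[1]) / diff(rng)
    slope <- diff(y) / diff(x)
    over <- which(slope > 1)
    df$is_super <- if (length(over) == 0L) FALSE else df$rank > over[1L]
  }
  rownames(df) <- NULL
  df
}

#' Codepletion of TF and BRD4 with H3K27ac loss and target expression
#'
#' Flags regions where both the transcription factor and BRD4 are
#' classified `"loss"` between baseline and perturbed conditions
#' ([classify_signal_change()]), sub-groups them by H3K27ac loss, attaches
#' the nearest gene and its log2 expression fold change, and compares the
#' with-loss and without-loss groups by a two-sided Wilcoxon rank-sum test.
#' Also reports the fraction of regions with reduced co-occupancy
#' (log2 perturbed/baseline < 0 for both factors).
#'
#' @param regions `GRanges` of TF binding-site regions with numeric
#'   metadata columns `tf_baseline`, `tf_perturbed`, `brd4_baseline`,
#'   `brd4_perturbed`, `k27ac_baseline`, `k27ac_perturbed`.
#' @param expression_fc Named numeric vector of per-gene log2 fold changes
#'   (perturbed vs baseline).
#' @param tss Data.frame with columns `gene`, `chrom`, `pos`.
#' @param eps Pseudocount for the co-occupancy log ratios (default 1).
#' @return List with `table` (per-region flags, nearest gene, log2 fold
#'   change), `median_with_loss`, `median_without_loss`, `rank_sum_p`, and
#'   `frac_reduced`.
#' @export
codepletion_and_expression <- function(regions, expression_fc, tss,
                                       eps = 1) {
  mc <- S4Vectors::mcols(regions)
  need <- c("tf_baseline", "tf_perturbed", "brd4_baseline",
            "brd4_perturbed", "k27ac_baseline", "k27ac_perturbed")
  miss <- setdiff(need, names(mc))
  if (length(miss)) stop("missing signal column(s): ",
                         paste(miss, collapse = ", "))
  tf_chg <- classify_signal_change(mc$tf_baseline, mc$tf_perturbed)
  brd4_chg <- classify_signal_change(mc$brd4_baseline, mc$brd4_perturbed)
  k27_chg <- classify_signal_change(mc$k27ac_baseline, mc$k27ac_perturbed)
  codepleted <- tf_chg == "loss" & brd4_chg == "loss"
  frac_reduced <- mean(
    log2((mc$tf_perturbed + eps) / (mc$tf_baseline + eps)) < 0 &
    log2((mc$brd4_perturbed + eps) / (mc$brd4_baseline + eps)) < 0)
  gene <- nearest_gene(regions, tss)
  tab <- data.frame(region = seq_along(regions), codepleted = codepleted,
                    k27ac_loss = k27_chg == "loss", gene = gene,
                    log2fc = unname(expression_fc[gene]),
                    stringsAsFactors = FALSE)
  with_loss <- tab$log2fc[tab$codepleted & tab$k27ac_loss]
  without_loss <- tab$log2fc[tab$codepleted & !tab$k27ac_loss]
  if (length(with_loss) == 0L || length(without_loss) == 0L) {
    warning("empty codepletion sub-group; rank-sum comparison skipped")
    p <- NA_real_
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(with_loss, without_loss)$p.value)
  }
  list(table = tab,
       median_with_loss = stats::median(with_loss),
       median_without_loss = stats::median(without_loss),
       rank_sum_p = p, frac_reduced = frac_reduced)
}
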