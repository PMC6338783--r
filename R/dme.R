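#' Construct a per-CpG methylome table
#'
#' A methylome is a data.frame of single-CpG observations with columns
#' `chrom`, `pos` (0-based CpG coordinate, BED frame), `beta` in [0, 1] and
#' `coverage` (reads), carrying `sample_id` and `condition` attributes.
#'
#' @param chrom,pos,beta,coverage Parallel vectors of CpG observations.
#' @param sample_id Sample identifier.
#' @param condition One of `"tumor"`, `"non_tumor"`, `"normal_reference"`.
#' @return A `cpg_methylome` data.frame sorted by chrom, pos.
#' @export
cpg_methylome <- function(chrom, pos, beta, coverage, sample_id,
                          condition = c("tumor", "non_tumor",
                                        "normal_reference")) {
  condition <- match.arg(condition)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta must lie in [0, 1]")
  if (any(coverage < 0)) stop("coverage must be >= 0")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   beta = as.numeric(beta), coverage = as.integer(coverage),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[, c("chrom", "pos")])) {
    stop("duplicated CpG positions within a methylome")
  }
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  attr(df, "condition") <- condition
  class(df) <- c("cpg_methylome", "data.frame")
  df
}

#' Pool several methylomes into one reference profile
#'
#' Per CpG, betas are averaged over the samples covering the site and
#' coverages are summed (total supporting reads), giving a single pooled
#' comparator profile.
#'
#' @param methylomes A `cpg_methylome` or list of them.
#' @param sample_id Identifier for the pooled profile.
#' @param condition Condition label for the pooled profile.
#' @return A `cpg_methylome`.
#' @export
pool_methylomes <- function(methylomes, sample_id = "pooled",
                            condition = "normal_reference") {
  if (inherits(methylomes, "cpg_methylome")) return(methylomes)
  stopifnot(is.list(methylomes), length(methylomes) >= 1L)
  all <- do.call(rbind, lapply(methylomes, function(m) {
    as.data.frame(m)[, c("chrom", "pos", "beta", "coverage")]
  }))
  key <- paste(all$chrom, all$pos, sep = ":")
  beta <- tapply(all$beta, key, mean)
  cov <- tapply(all$coverage, key, sum)
  first <- !duplicated(key)
  ord <- key[first]
  cpg_methylome(all$chrom[first], all$pos[first],
                as.numeric(beta[ord]), as.integer(cov[ord]),
                sample_id = sample_id, condition = condition)
}

#' Per-enhancer beta vectors from a methylome
#'
#' Collects, for every enhancer, the betas of CpGs falling inside the
#' interval (half-open: a CpG at the BED start is included, one at the BED
#' end is excluded) with coverage at least `min_coverage`, in positional
#' order.
#'
#' @param methylome A `cpg_methylome`.
#' @param enhancers `GRanges` of enhancer intervals.
#' @param min_coverage Minimum reads for a CpG to qualify (default 5).
#' @return Named list of numeric beta vectors, one per enhancer (names from
#'   the `name` metadata column or positional ids); enhancers without
#'   qualifying CpGs yield empty vectors.
#' @export
enhancer_betas <- function(methylome, enhancers, min_coverage = 5L) {
  if (length(enhancers) == 0L) stop("enhancers must be non-empty")
  nm <- if ("name" %in% names(S4Vectors::mcols(enhancers)) &&
            !anyDuplicated(enhancers$name)) enhancers$name else
    paste0("enh_", seq_along(enhancers))
  m <- as.data.frame(methylome)
  m <- m[m$coverage >= min_coverage, , drop = FALSE]
  out <- stats::setNames(rep(list(numeric(0)), length(enhancers)), nm)
  if (nrow(m) == 0L) return(out)
  sites <- GenomicRanges::GRanges(m$chrom,
                                  IRanges::IRanges(m$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(sites, enhancers, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (j in unique(s)) {
    idx <- q[s == j]
    out[[j]] <- m$beta[idx[order(m$pos[idx])]]
  }
  out
}

#' Call differentially methylated enhancers from per-CpG betas
#'
#' Per enhancer, per-CpG deltas (tumor beta - reference beta) are formed at
#' CpG positions covered with at least `min_coverage` reads in both
#' profiles; an enhancer is emitted as a DME when at least `min_cpgs` such
#' CpGs exist and the absolute mean delta is at least `min_delta`
#' (direction from the sign of the mean). The stricter per-site reading -
#' requiring every one of `min_cpgs` CpGs to individually change by
#' `min_delta` - is available behind `per_site_rule = TRUE`.
#'
#' @param tumor,reference A `cpg_methylome` or list of them (lists are
#'   pooled with [pool_methylomes()]).
#' @param enhancers `GRanges` of enhancer intervals.
#' @param min_delta Minimum absolute mean beta change (default 0.1).
#' @param min_cpgs Minimum number of shared qualifying CpGs (default 10).
#' @param min_coverage Minimum per-CpG coverage in each profile (default 5).
#' @param per_site_rule Require |delta| >= min_delta at every used CpG.
#' @return Data.frame with columns `enhancer`, `n_cpgs_used`, `mean_delta`,
#'   `direction`, plus a list-column `per_cpg_deltas`.
#' @export
call_dmes <- function(tumor, reference, enhancers, min_delta = 0.1,
                      min_cpgs = 10L, min_coverage = 5L,
                      per_site_rule = FALSE) {
  if (min_delta <= 0) stop("min_delta must be > 0")
  if (min_cpgs < 1L) stop("min_cpgs must be >= 1")
  tumor <- pool_methylomes(tumor, sample_id = "tumor_pool",
                           condition = "tumor")
  reference <- pool_methylomes(reference)
  tm <- as.data.frame(tumor)
  rm_ <- as.data.frame(reference)
  tm <- tm[tm$coverage >= min_coverage, , drop = FALSE]
  rm_ <- rm_[rm_$coverage >= min_coverage, , drop = FALSE]
  merged <- merge(tm, rm_, by = c("chrom", "pos"),
                  suffixes = c("_t", "_r"))
  merged$delta <- merged$beta_t - merged$beta_r
  nm <- if ("name" %in% names(S4Vectors::mcols(enhancers)) &&
            !anyDuplicated(enhancers$name)) enhancers$name else
    paste0("enh_", seq_along(enhancers))
  sites <- GenomicRanges::GRanges(merged$chrom,
                                  IRanges::IRanges(merged$pos + 1L,
                                                   width = 1L))
  hits <- GenomicRanges::findOverlaps(sites, enhancers, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  recs <- list()
  for (j in unique(s)) {
    idx <- q[s == j]
    idx <- idx[order(merged$pos[idx])]
    deltas <- merged$delta[idx]
    n <- length(deltas)
    if (n < min_cpgs) next
    md <- mean(deltas)
    pass <- if (per_site_rule) all(abs(deltas) >= min_delta) else
      abs(md) >= min_delta
    if (!pass) next
    recs[[length(recs) + 1L]] <- data.frame(
      enhancer = nm[j], n_cpgs_used = n, mean_delta = md,
      direction = if (md < 0) "hypo" else "hyper",
      stringsAsFactors = FALSE)
    recs[[length(recs)]]$per_cpg_deltas <- list(deltas)
  }
  if (length(recs) == 0L) {
    out <- data.frame(enhancer = character(0), n_cpgs_used = integer(0),
                      mean_delta = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
    out$per_cpg_deltas <- list()
    return(out)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Count DME calls by direction
#'
#' @param dmes Data.frame from [call_dmes()].
#' @return Named integer vector `c(n_hypo, n_hyper)`.
#' @export
dme_direction_summary <- function(dmes) {
  c(n_hypo = sum(dmes$direction == "hypo"),
    n_hyper = sum(dmes$direction == "hyper"))
}
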