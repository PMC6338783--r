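#' Pair enhancers with candidate target genes by eRNA-mRNA correlation
#'
#' For each candidate (enhancer, gene) pair, computes the Pearson
#' correlation between the enhancer's eRNA and the gene's mRNA across the
#' shared sample columns and keeps pairs with r >= `r_min`. Candidates are
#' expected to be pre-restricted to a genomic distance window (the bundled
#' pipeline uses nearest-gene candidates); pairs with a constant expression
#' vector are skipped with a warning since r is undefined there.
#'
#' @param erna Numeric matrix, enhancers x samples (rownames = enhancers).
#' @param mrna Numeric matrix, genes x samples (rownames = genes).
#' @param candidates Data.frame with columns `enhancer`, `gene`.
#' @param r_min Minimum Pearson r to keep a pair (default 0.3).
#' @return Data.frame with columns `enhancer`, `gene`, `erna_mrna_r`,
#'   `erna_mrna_p`, `n_samples`.
#' @export
pair_enhancers_to_genes <- function(erna, mrna, candidates, r_min = 0.3) {
  stopifnot(all(c("enhancer", "gene") %in% names(candidates)))
  shared <- intersect(colnames(erna), colnames(mrna))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    enh <- candidates$enhancer[i]; gene <- candidates$gene[i]
    if (!enh %in% rownames(erna) || !gene %in% rownames(mrna)) return(NULL)
    x <- erna[enh, shared]; y <- mrna[gene, shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant expression vector for pair ", enh, " - ", gene,
              "; skipped")
      return(NULL)
    }
    ct <- pearson_test(x, y)
    data.frame(enhancer = enh, gene = gene, erna_mrna_r = ct$r,
               erna_mrna_p = ct$p_value, n_samples = ct$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enhancer = character(0), gene = character(0),
                      erna_mrna_r = numeric(0), erna_mrna_p = numeric(0),
                      n_samples = integer(0))
  }
  out <- out[out$erna_mrna_r >= r_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen DMEs for inverse methylation-expression coupling
#'
#' For every DME that has a paired target gene, computes the Pearson
#' correlation between per-sample enhancer methylation and target mRNA over
#' the pooled tumor + non-tumor samples and emits a hit when r < 0 with a
#' one-sided (negative-direction) p-value below `alpha`. The inverse
#' direction is prespecified - enhancer hypomethylation with target
#' up-regulation and hypermethylation with down-regulation both manifest as
#' a negative methylation-expression correlation - which is why the test is
#' one-sided and its null hit rate equals `alpha`.
#'
#' @param dmes Data.frame from [call_dmes()].
#' @param enhancer_meth Numeric matrix, enhancers x samples, of per-sample
#'   mean enhancer methylation (beta).
#' @param mrna Numeric matrix, genes x samples.
#' @param pairs Data.frame from [pair_enhancers_to_genes()].
#' @param alpha Significance cutoff (default 0.05).
#' @return Data.frame with the DME fields plus `gene`, `erna_mrna_r`,
#'   `meth_expr_r`, `meth_expr_p`.
#' @export
screen_inverse_dmes <- function(dmes, enhancer_meth, mrna, pairs,
                                alpha = 0.05) {
  shared <- intersect(colnames(enhancer_meth), colnames(mrna))
  if (length(shared) < 3L) stop("need at least 3 paired samples")
  rows <- lapply(seq_len(nrow(dmes)), function(i) {
    enh <- dmes$enhancer[i]
    pr <- pairs[pairs$enhancer == enh, , drop = FALSE]
    if (nrow(pr) == 0L || !enh %in% rownames(enhancer_meth)) return(NULL)
    hits <- lapply(seq_len(nrow(pr)), function(k) {
      gene <- pr$gene[k]
      if (!gene %in% rownames(mrna)) return(NULL)
      x <- enhancer_meth[enh, shared]; y <- mrna[gene, shared]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
      ct <- pearson_test(x, y, alternative = "less")
      if (ct$r < 0 && ct$p_value < alpha) {
        data.frame(enhancer = enh, gene = gene,
                   n_cpgs_used = dmes$n_cpgs_used[i],
                   mean_delta = dmes$mean_delta[i],
                   direction = dmes$direction[i],
                   erna_mrna_r = pr$erna_mrna_r[k],
                   meth_expr_r = ct$r, meth_expr_p = ct$p_value,
                   stringsAsFactors = FALSE)
      } else NULL
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enhancer = character(0), gene = character(0),
                      n_cpgs_used = integer(0), mean_delta = numeric(0),
                      direction = character(0), erna_mrna_r = numeric(0),
                      meth_expr_r = numeric(0), meth_expr_p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Rank candidate target genes by supporting DMEs
#'
#' Genes are ranked by the number of distinct supporting DMEs (descending),
#' then by the maximum absolute eRNA-mRNA correlation among their pairs,
#' with residual ties broken lexicographically by gene name.
#'
#' @param hits Data.frame from [screen_inverse_dmes()].
#' @return Data.frame with columns `gene`, `n_dmes`, `max_abs_r`, ordered
#'   by rank.
#' @export
rank_targets <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene = character(0), n_dmes = integer(0),
                      max_abs_r = numeric(0)))
  }
  genes <- unique(hits$gene)
  tab <- data.frame(
    gene = genes,
    n_dmes = vapply(genes, function(g)
      length(unique(hits$enhancer[hits$gene == g])), 0L),
    max_abs_r = vapply(genes, function(g)
      max(abs(hits$erna_mrna_r[hits$gene == g])), 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_dmes, -tab$max_abs_r, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
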