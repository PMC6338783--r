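#' Configuration of planted effects for the synthetic cohort
#'
#' Bundles the effect sizes, noise levels and sample sizes of the
#' simulated paired tumor/non-tumor cohort. Defaults describe the study
#' conditions the package is designed around: 33 tumor/non-tumor pairs, a
#' minority of regions differentially methylated with 95.5% of planted
#' differentially methylated enhancers hypomethylated, a mean planted beta
#' shift of 0.15 (non-tumor enhancer baseline 0.55, planted hypo tumors
#' near 0.40, promoters near 0.02), ~17.6 reads per CpG, enhancer
#' methylation coupled to eRNA at r = -0.8, eRNA coupled to target mRNA at
#' r = +0.86, and a hazard ratio of 4.404 (overall) / 3.809 (disease-free)
#' for the strong- vs weak-hypomethylation stratum.
#'
#' @param n_pairs Number of tumor/non-tumor pairs (default 33).
#' @param n_genes,n_enhancers Size of the synthetic annotation.
#' @param frac_dm_regions Fraction of enhancers with a planted methylation
#'   shift (default 0.1).
#' @param frac_hypo_among_dm Fraction of planted DM enhancers that are
#'   hypomethylated (default 0.955).
#' @param delta_beta Magnitude of the planted mean beta shift (default
#'   0.15; hypo = -delta, hyper = +delta).
#' @param beta_noise_sd Biological per-sample beta noise SD (default 0.02).
#' @param min_cpgs_per_enhancer Minimum CpGs per enhancer (default 12).
#' @param coverage_mean Mean reads per CpG (default 17.6).
#' @param erna_coupling Correlation between enhancer methylation and eRNA
#'   (default -0.8).
#' @param mrna_coupling Correlation between eRNA and target mRNA
#'   (default +0.86).
#' @param true_hr,true_hr_dfs Hazard ratios of the strong- vs
#'   weak-hypomethylation stratum for the overall and disease-free
#'   endpoints (defaults 4.404 and 3.809).
#' @param n_wgbs_tumor,n_wgbs_normal Profiles entering the pooled WGBS-style
#'   comparison (defaults 3 and 3).
#' @param enhancer_baseline,promoter_baseline Non-tumor beta baselines
#'   (defaults 0.55 and 0.02).
#' @param n_regions Regions in the capture-style coverage matrix
#'   (default 1000).
#' @param mbd_noise_sd Log2-scale noise SD of the coverage signal
#'   (default 0.25).
#' @param dmr_shift Planted log2 shift in tumor coverage signal (default
#'   0.75, i.e. 3 noise SDs).
#' @param frac_hypo_among_dmr Fraction of planted coverage-level DMRs that
#'   are hypomethylated (default 0.63).
#' @param seed Integer seed.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(n_pairs = 33L, n_genes = 40L, n_enhancers = 200L,
                          frac_dm_regions = 0.1,
                          frac_hypo_among_dm = 0.955, delta_beta = 0.15,
                          beta_noise_sd = 0.02,
                          min_cpgs_per_enhancer = 12L,
                          coverage_mean = 17.6, erna_coupling = -0.8,
                          mrna_coupling = 0.86, true_hr = 4.404,
                          true_hr_dfs = 3.809, n_wgbs_tumor = 3L,
                          n_wgbs_normal = 3L, enhancer_baseline = 0.55,
                          promoter_baseline = 0.02, n_regions = 1000L,
                          mbd_noise_sd = 0.25, dmr_shift = 0.75,
                          frac_hypo_among_dmr = 0.63, seed = 1L) {
  fracs <- c(frac_dm_regions, frac_hypo_among_dm, frac_hypo_among_dmr)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  if (coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (abs(erna_coupling) >= 1 || abs(mrna_coupling) >= 1) {
    stop("couplings must lie in (-1, 1)")
  }
  if (true_hr <= 0 || true_hr_dfs <= 0) stop("hazard ratios must be > 0")
  cfg <- as.list(environment())
  class(cfg) <- "effect_config"
  cfg
}

.gr0 <- function(chrom, start0, end0, name, cls) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         name = name, element_class = cls)
}

#' Build a synthetic annotated chromosome
#'
#' Lays out non-overlapping promoters (TSS +/- 2 kb), gene bodies,
#' enhancers (always more than 2 kb from any TSS) and intergenic filler on
#' a single synthetic chromosome, and assigns every enhancer (and
#' promoter) a set of CpG positions. TSS coordinates and per-element CpG
#' sites are stored in `metadata()` under `tss` and `cpg_sites`.
#'
#' @param n_genes,n_enhancers Element counts (>= 1).
#' @param seed Integer seed for CpG placement.
#' @param min_cpgs_per_enhancer Minimum CpG count per enhancer.
#' @param chrom Chromosome name.
#' @param chrom_length Optional fixed chromosome length in bp; an error is
#'   raised when the requested elements do not fit.
#' @param enhancer_width,gene_body_length,promoter_halfwidth,gap Layout
#'   dimensions in bp.
#' @return `GRanges` annotation with `name` and `element_class`.
#' @export
make_annotation <- function(n_genes, n_enhancers, seed = 1L,
                            min_cpgs_per_enhancer = 12L, chrom = "chrS",
                            chrom_length = NULL, enhancer_width = 1500L,
                            gene_body_length = 6000L,
                            promoter_halfwidth = 2000L, gap = 3000L) {
  if (n_genes < 1L || n_enhancers < 1L) {
    stop("n_genes and n_enhancers must be >= 1")
  }
  set.seed(seed)
  cursor <- 1000
  rows <- list()
  tss <- data.frame(gene = character(0), chrom = character(0),
                    pos = numeric(0), stringsAsFactors = FALSE)
  g <- 0L; e <- 0L
  add <- function(start0, end0, name, cls) {
    rows[[length(rows) + 1L]] <<- data.frame(start0 = start0, end0 = end0,
                                             name = name, cls = cls,
                                             stringsAsFactors = FALSE)
  }
  # interleave genes and enhancers so enhancers have nearby but distal TSS
  per_gene <- ceiling(n_enhancers / n_genes)
  while (g < n_genes || e < n_enhancers) {
    if (g < n_genes) {
      g <- g + 1L
      t0 <- cursor + promoter_halfwidth
      add(cursor, t0 + promoter_halfwidth, sprintf("prom_%03d", g),
          "promoter")
      add(t0 + promoter_halfwidth,
          t0 + promoter_halfwidth + gene_body_length,
          sprintf("gene_%03d", g), "gene_body")
      tss <- rbind(tss, data.frame(gene = sprintf("gene_%03d", g),
                                   chrom = chrom, pos = t0 + 1,
                                   stringsAsFactors = FALSE))
      body_end <- t0 + promoter_halfwidth + gene_body_length
      add(body_end, body_end + gap,
          sprintf("inter_%04d", length(rows)), "intergenic")
      cursor <- body_end + gap
    }
    k <- 0L
    while (e < n_enhancers && (k < per_gene || g >= n_genes)) {
      e <- e + 1L; k <- k + 1L
      s0 <- cursor + 500
      add(cursor, s0, sprintf("inter_%04d", length(rows)), "intergenic")
      add(s0, s0 + enhancer_width, sprintf("enh_%04d", e), "enhancer")
      add(s0 + enhancer_width, s0 + enhancer_width + gap,
          sprintf("inter_%04d", length(rows)), "intergenic")
      cursor <- s0 + enhancer_width + gap
    }
  }
  total <- cursor + 1000
  if (!is.null(chrom_length) && chrom_length < total) {
    stop("requested elements exceed chromosome capacity: need ", total,
         " bp, have ", chrom_length)
  }
  df <- do.call(rbind, rows)
  gr <- .gr0(chrom, df$start0, df$end0, df$name, df$cls)
  # CpG placement: dense inside enhancers/promoters, none elsewhere
  cpg <- lapply(seq_along(gr), function(i) {
    cls <- gr$element_class[i]
    if (!cls %in% c("enhancer", "promoter")) return(NULL)
    n_cpg <- if (cls == "enhancer") {
      min_cpgs_per_enhancer + stats::rpois(1L, 3)
    } else 8L
    s0 <- GenomicRanges::start(gr)[i] - 1L
    w <- GenomicRanges::width(gr)[i]
    pos <- sort(sample.int(w, n_cpg) - 1L + s0)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)[i]),
               pos = pos, element = gr$name[i],
               element_class = cls, stringsAsFactors = FALSE)
  })
  S4Vectors::metadata(gr) <- list(
    tss = tss, cpg_sites = do.call(rbind, cpg),
    chrom_length = if (is.null(chrom_length)) total else chrom_length)
  gr
}

.plant_effects <- function(enhancer_names, frac_dm, frac_hypo, delta,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(enhancer_names)
  planted <- rep(FALSE, n)
  planted[sample.int(n, round(frac_dm * n))] <- TRUE
  direction <- rep(NA_character_, n)
  direction[planted] <- ifelse(stats::runif(sum(planted)) < frac_hypo,
                               "hypo", "hyper")
  data.frame(region = enhancer_names, planted = planted,
             direction = direction,
             delta = ifelse(planted,
                            ifelse(direction == "hypo", -delta, delta), 0),
             stringsAsFactors = FALSE)
}

.draw_betas <- function(base, noise_sd, coverage_mean) {
  n <- length(base)
  if (noise_sd == 0) {
    # noise-free mode: no biological noise and no read sampling, so the
    # observed beta equals the planted baseline exactly
    coverage <- rep(max(1L, as.integer(round(coverage_mean))), n)
    return(list(beta = base, coverage = coverage))
  }
  sd_logit <- noise_sd / pmax(base * (1 - base), 0.05)
  p <- stats::plogis(stats::qlogis(base) + stats::rnorm(n, 0, sd_logit))
  coverage <- 1L + stats::rpois(n, max(coverage_mean - 1, 0))
  beta <- stats::rbinom(n, coverage, p) / coverage
  list(beta = beta, coverage = coverage)
}

#' Simulate paired per-CpG methylomes with planted enhancer effects
#'
#' Per-CpG betas are drawn logit-normally around element baselines
#' (non-tumor enhancers 0.55, promoters 0.02), then observed through
#' binomial read sampling at the configured coverage. A fraction of
#' enhancers carries a planted tumor shift of `-delta_beta`
#' (hypomethylation, with probability `frac_hypo_among_dm`) or
#' `+delta_beta`, applied uniformly to every tumor. Shifted baselines are
#' clipped into [0.02, 0.98] and flagged in the truth table. Setting
#' `beta_noise_sd = 0` switches off both the biological noise and the
#' binomial read sampling, yielding noise-free observed betas.
#'
#' @param annotation `GRanges` from [make_annotation()] (with CpG sites in
#'   its metadata).
#' @param cfg An [effect_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `tumor` and `non_tumor` (lists of `n_pairs`
#'   [cpg_methylome()]s), `normal` (list of `n_wgbs_normal` reference
#'   methylomes), and `truth` (per-enhancer planted effects with
#'   `target_gene`).
#' @export
simulate_methylomes <- function(annotation, cfg, seed = cfg$seed) {
  set.seed(seed)
  sites <- S4Vectors::metadata(annotation)$cpg_sites
  tssdf <- S4Vectors::metadata(annotation)$tss
  if (is.null(sites)) stop("annotation carries no CpG sites")
  enh <- annotation[annotation$element_class == "enhancer"]
  truth <- .plant_effects(enh$name, cfg$frac_dm_regions,
                          cfg$frac_hypo_among_dm, cfg$delta_beta)
  truth$target_gene <- nearest_gene(enh, tssdf)
  base <- ifelse(sites$element_class == "enhancer",
                 cfg$enhancer_baseline, cfg$promoter_baseline)
  delta_site <- truth$delta[match(sites$element, truth$region)]
  delta_site[is.na(delta_site)] <- 0
  clip <- function(x) pmin(0.98, pmax(0.02, x))
  bt <- clip(base + delta_site)
  tumor <- vector("list", cfg$n_pairs)
  non_tumor <- vector("list", cfg$n_pairs)
  for (j in seq_len(cfg$n_pairs)) {
    dt <- .draw_betas(bt, cfg$beta_noise_sd, cfg$coverage_mean)
    tumor[[j]] <- cpg_methylome(sites$chrom, sites$pos, dt$beta,
                                dt$coverage,
                                sample_id = sprintf("T%02d", j),
                                condition = "tumor")
    dn <- .draw_betas(base, cfg$beta_noise_sd, cfg$coverage_mean)
    non_tumor[[j]] <- cpg_methylome(sites$chrom, sites$pos, dn$beta,
                                    dn$coverage,
                                    sample_id = sprintf("N%02d", j),
                                    condition = "non_tumor")
  }
  normal <- lapply(seq_len(cfg$n_wgbs_normal), function(j) {
    d <- .draw_betas(base, cfg$beta_noise_sd, cfg$coverage_mean)
    cpg_methylome(sites$chrom, sites$pos, d$beta, d$coverage,
                  sample_id = sprintf("R%02d", j),
                  condition = "normal_reference")
  })
  truth$clipped <- truth$planted &
    (cfg$enhancer_baseline + truth$delta > 0.98 |
       cfg$enhancer_baseline + truth$delta < 0.02)
  list(tumor = tumor, non_tumor = non_tumor, normal = normal,
       truth = truth)
}

#' Per-sample mean enhancer methylation matrix
#'
#' @param methylomes List of [cpg_methylome()]s.
#' @param enhancers `GRanges` of enhancers.
#' @param min_coverage Per-CpG coverage filter (default 5).
#' @return Numeric matrix, enhancers x samples, of mean betas (NA when an
#'   enhancer has no qualifying CpG in a sample).
#' @export
enhancer_meth_matrix <- function(methylomes, enhancers, min_coverage = 5L) {
  cols <- lapply(methylomes, function(m) {
    vapply(enhancer_betas(m, enhancers, min_coverage), function(b) {
      if (length(b)) mean(b) else NA_real_
    }, 0)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- vapply(methylomes, function(m) attr(m, "sample_id"), "")
  mat
}

#' Simulate coupled eRNA and mRNA expression
#'
#' Per enhancer, eRNA is generated so its population correlation with the
#' per-sample enhancer methylation equals `erna_coupling` (negative by
#' default: hypomethylation increases eRNA); target-gene mRNA is generated
#' from the eRNA of its first paired enhancer at correlation
#' `mrna_coupling`. Genes without a paired enhancer are independent noise.
#' The generated eRNA models the sense-strand unidirectional transcript;
#' antisense signal is background noise and not represented.
#'
#' @param enh_meth Numeric matrix, enhancers x samples, of per-sample mean
#'   enhancer methylation (see [enhancer_meth_matrix()]).
#' @param targets Named character vector mapping enhancer name to target
#'   gene.
#' @param cfg An [effect_config()].
#' @param extra_genes Optional character vector of unpaired noise genes.
#' @param seed Optional seed.
#' @return List with matrices `erna` (enhancers x samples) and `mrna`
#'   (genes x samples).
#' @export
simulate_expression <- function(enh_meth, targets, cfg,
                                extra_genes = character(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(cfg$erna_coupling) >= 1 || abs(cfg$mrna_coupling) >= 1) {
    stop("couplings must lie in (-1, 1)")
  }
  ns <- ncol(enh_meth)
  zrow <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  rho <- cfg$erna_coupling
  erna <- t(apply(enh_meth, 1L, function(m) {
    5 + rho * zrow(m) + sqrt(1 - rho^2) * stats::rnorm(ns)
  }))
  dimnames(erna) <- dimnames(enh_meth)
  rho2 <- cfg$mrna_coupling
  genes <- unique(c(unname(targets), extra_genes))
  mrna <- matrix(NA_real_, length(genes), ns,
                 dimnames = list(genes, colnames(enh_meth)))
  for (g in genes) {
    paired <- names(targets)[targets == g]
    paired <- paired[paired %in% rownames(erna)]
    if (length(paired)) {
      ez <- zrow(erna[paired[1L], ])
      mrna[g, ] <- 5 + rho2 * ez + sqrt(1 - rho2^2) * stats::rnorm(ns)
    } else {
      mrna[g, ] <- 5 + stats::rnorm(ns)
    }
  }
  list(erna = erna, mrna = mrna)
}

#' Simulate a capture-style region coverage matrix with planted DMRs
#'
#' Region counts are Poisson draws around log-normal per-region levels
#' with per-sample depth factors; a planted fraction of regions carries a
#' log2 shift of `-dmr_shift` (hypomethylation, probability
#' `frac_hypo_among_dmr`) or `+dmr_shift` in the tumor columns.
#'
#' @param cfg An [effect_config()].
#' @param n_regions Number of regions (default `cfg$n_regions`).
#' @param frac_dm Planted fraction (default `cfg$frac_dm_regions`).
#' @param seed Optional seed.
#' @return List with `counts` (regions x samples), `pairs` (tumor /
#'   non_tumor column names) and `truth`.
#' @export
simulate_region_signal <- function(cfg, n_regions = cfg$n_regions,
                                   frac_dm = cfg$frac_dm_regions,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_regions
  truth <- .plant_effects(sprintf("region_%05d", seq_len(n)), frac_dm,
                          cfg$frac_hypo_among_dmr, cfg$dmr_shift)
  mu <- stats::runif(n, 4, 10)
  tum <- sprintf("T%02d", seq_len(cfg$n_pairs))
  non <- sprintf("N%02d", seq_len(cfg$n_pairs))
  depth <- stats::runif(2 * cfg$n_pairs, 0.7, 1.3)
  counts <- matrix(0L, n, 2 * cfg$n_pairs,
                   dimnames = list(truth$region, c(tum, non)))
  for (j in seq_len(2 * cfg$n_pairs)) {
    shift <- if (j <= cfg$n_pairs) truth$delta else 0
    lam <- 2^(mu + shift + stats::rnorm(n, 0, cfg$mbd_noise_sd)) * depth[j]
    counts[, j] <- stats::rpois(n, lam)
  }
  list(counts = counts, pairs = data.frame(tumor = tum, non_tumor = non,
                                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate histone-mark and factor-occupancy tracks
#'
#' Active enhancers get high H3K27ac and H3K4me1 with low H3K4me3 and
#' H3K27me3 over a log-normal local background; promoters get high
#' H3K4me3. Transcription-factor binding sites (the active enhancers)
#' carry TF and BRD4 occupancy; in the perturbed (knockout) condition a
#' planted fraction of them loses >= 50% of TF and BRD4 signal, and a
#' sub-fraction of those additionally loses H3K27ac. A configurable number
#' of adjacent-enhancer clusters is boosted to >= 10x median signal to
#' form planted super-enhancers. Genes nearest to K27ac-loss codepleted
#' enhancers get planted negative expression log2 fold changes.
#'
#' @param annotation `GRanges` from [make_annotation()].
#' @param cfg An [effect_config()].
#' @param active_frac Fraction of enhancers that are active (default 0.6).
#' @param tf_loss_frac Fraction of TF binding sites losing TF and BRD4 in
#'   the perturbed condition (default 0.842).
#' @param k27ac_loss_frac Fraction of codepleted sites that additionally
#'   lose H3K27ac (default 0.6, putting the overall fraction of enhancers
#'   losing H3K27ac near 30%).
#' @param n_se_clusters,se_size Planted super-enhancer clusters (default 2
#'   clusters of 5 adjacent enhancers).
#' @param seed Optional seed.
#' @return List with `regions` (`GRanges` with per-mark baseline/perturbed
#'   signal and truth flags `active`, `tf_loss`, `k27ac_loss`,
#'   `se_cluster`), `expression_fc` (named per-gene log2 fold changes) and
#'   `tss`.
#' @export
simulate_chip_tracks <- function(annotation, cfg, active_frac = 0.6,
                                 tf_loss_frac = 0.842,
                                 k27ac_loss_frac = 0.6,
                                 n_se_clusters = 2L, se_size = 5L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tssdf <- S4Vectors::metadata(annotation)$tss
  keep <- annotation$element_class %in% c("enhancer", "promoter")
  gr <- annotation[keep]
  n <- length(gr)
  is_enh <- gr$element_class == "enhancer"
  bg <- stats::rlnorm(n, 0, 0.1)
  active <- is_enh & stats::runif(n) < active_frac
  ln <- function(mu) stats::rlnorm(n, log(mu), 0.15)
  k27ac <- bg * ifelse(active, ln(6), ifelse(is_enh, ln(1), ln(3)))
  k4me1 <- bg * ifelse(active, ln(4), ifelse(is_enh, ln(1.2), ln(1)))
  k4me3 <- bg * ifelse(is_enh, ln(0.5), ln(6))
  k27me3 <- bg * ln(0.4)
  # planted super-enhancer clusters: runs of adjacent active enhancers
  se_cluster <- rep(NA_integer_, n)
  enh_idx <- which(is_enh)
  if (n_se_clusters > 0L && length(enh_idx) >= se_size) {
    starts <- seq(1L, length(enh_idx) - se_size + 1L,
                  length.out = n_se_clusters)
    for (k in seq_len(n_se_clusters)) {
      members <- enh_idx[floor(starts[k]) + seq_len(se_size) - 1L]
      se_cluster[members] <- k
      active[members] <- TRUE
      k27ac[members] <- 10 * stats::median(k27ac) *
        stats::rlnorm(se_size, 0, 0.1)
    }
  }
  tf_base <- bg * ifelse(active, ln(4), ln(1))
  brd4_base <- bg * ifelse(active, ln(4), ln(1))
  tf_loss <- active & stats::runif(n) < tf_loss_frac
  k27ac_loss <- tf_loss & stats::runif(n) < k27ac_loss_frac
  lose <- function(base, hit, factor_hit = 0.2, factor_keep = 1) {
    base * ifelse(hit, factor_hit * stats::rlnorm(n, 0, 0.05),
                  factor_keep * stats::rlnorm(n, 0, 0.05))
  }
  tf_pert <- lose(tf_base, tf_loss)
  brd4_pert <- lose(brd4_base, tf_loss)
  k27ac_pert <- lose(k27ac, k27ac_loss, factor_hit = 0.3)
  S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr), S4Vectors::DataFrame(
    background = bg, H3K27ac = k27ac, H3K4me1 = k4me1, H3K4me3 = k4me3,
    H3K27me3 = k27me3, tf_baseline = tf_base, tf_perturbed = tf_pert,
    brd4_baseline = brd4_base, brd4_perturbed = brd4_pert,
    k27ac_baseline = k27ac, k27ac_perturbed = k27ac_pert,
    active = active, tf_loss = tf_loss, k27ac_loss = k27ac_loss,
    se_cluster = se_cluster))
  genes <- unique(tssdf$gene)
  fc <- stats::setNames(stats::rnorm(length(genes), 0, 0.3), genes)
  hit_genes <- unique(nearest_gene(gr[tf_loss & k27ac_loss], tssdf))
  hit_genes <- hit_genes[!is.na(hit_genes)]
  fc[hit_genes] <- stats::rnorm(length(hit_genes), -1.2, 0.3)
  list(regions = gr, expression_fc = fc, tss = tssdf)
}

#' Simulate stratified survival outcomes
#'
#' Patients are split at the median of their hypomethylation score (more
#' negative = stronger hypomethylation); event times are exponential with
#' the baseline hazard multiplied by `true_hr` for the
#' strong-hypomethylation half, under independent uniform censoring.
#'
#' @param score Numeric per-patient relative-methylation score.
#' @param cfg An [effect_config()]; `cfg$true_hr` is the planted hazard
#'   ratio.
#' @param true_hr Hazard ratio override (default `cfg$true_hr`).
#' @param base_hazard Baseline hazard per month (default 0.02).
#' @param censor_max Upper bound of the uniform censoring time
#'   (default 120 months).
#' @param seed Optional seed.
#' @return Data.frame with `patient`, `time`, `event`, `stratum`,
#'   `relative_methylation`.
#' @export
simulate_survival <- function(score, cfg, true_hr = cfg$true_hr,
                              base_hazard = 0.02, censor_max = 120,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (true_hr <= 0) stop("true_hr must be > 0")
  n <- length(score)
  stratum <- stratify_by_hypomethylation(score)
  hazard <- base_hazard * ifelse(stratum == "strong_hypo", true_hr, 1)
  t_event <- stats::rexp(n, hazard)
  t_cens <- stats::runif(n, 0, censor_max)
  data.frame(patient = sprintf("P%02d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stratum = stratum, relative_methylation = score,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Orchestrates the generator: annotation, paired methylomes with planted
#' enhancer effects, capture-style region coverage with planted DMRs,
#' coupled eRNA/mRNA expression, histone-mark tracks, and survival
#' outcomes driven by per-patient relative methylation at the planted hypo
#' enhancers. Fixing `cfg$seed` reproduces the cohort exactly.
#'
#' @param cfg An [effect_config()].
#' @return List with `annotation`, `methylomes`, `region_signal`,
#'   `enh_meth` (enhancers x all samples), `expression`, `chip`,
#'   `survival_os`, `survival_dfs`, `truth`.
#' @export
simulate_cohort <- function(cfg = effect_config()) {
  anno <- make_annotation(cfg$n_genes, cfg$n_enhancers,
                          seed = cfg$seed,
                          min_cpgs_per_enhancer = cfg$min_cpgs_per_enhancer)
  meth <- simulate_methylomes(anno, cfg, seed = cfg$seed + 1L)
  enh <- anno[anno$element_class == "enhancer"]
  enh_meth <- enhancer_meth_matrix(c(meth$tumor, meth$non_tumor), enh)
  # planted enhancers drive their target gene's mRNA: list them first so
  # simulate_expression picks them as the primary enhancer per gene
  truth_ord <- meth$truth[order(!meth$truth$planted), , drop = FALSE]
  targets <- stats::setNames(truth_ord$target_gene, truth_ord$region)
  expr <- simulate_expression(enh_meth, targets, cfg,
                              seed = cfg$seed + 2L)
  sig <- simulate_region_signal(cfg, seed = cfg$seed + 3L)
  chip <- simulate_chip_tracks(anno, cfg, seed = cfg$seed + 4L)
  planted_hypo <- meth$truth$region[meth$truth$planted &
                                      meth$truth$direction == "hypo"]
  tum_ids <- sprintf("T%02d", seq_len(cfg$n_pairs))
  non_ids <- sprintf("N%02d", seq_len(cfg$n_pairs))
  if (length(planted_hypo)) {
    rel <- 100 * (colMeans(enh_meth[planted_hypo, tum_ids, drop = FALSE],
                           na.rm = TRUE) -
                    colMeans(enh_meth[planted_hypo, non_ids,
                                      drop = FALSE], na.rm = TRUE))
  } else {
    rel <- stats::rnorm(cfg$n_pairs)
  }
  surv_os <- simulate_survival(unname(rel), cfg, true_hr = cfg$true_hr,
                               seed = cfg$seed + 5L)
  surv_dfs <- simulate_survival(unname(rel), cfg,
                                true_hr = cfg$true_hr_dfs,
                                seed = cfg$seed + 6L)
  list(annotation = anno, methylomes = meth, region_signal = sig,
       enh_meth = enh_meth, expression = expr, chip = chip,
       survival_os = surv_os, survival_dfs = surv_dfs,
       truth = meth$truth)
}
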