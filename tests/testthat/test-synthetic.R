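test_that("make_annotation lays out disjoint elements with distal
           enhancers and enough CpGs", {
  anno <- make_annotation(1, 1, seed = 1)
  expect_equal(sum(anno$element_class == "promoter"), 1)
  expect_equal(sum(anno$element_class == "gene_body"), 1)
  expect_equal(sum(anno$element_class == "enhancer"), 1)

  anno <- make_annotation(8, 30, seed = 2, min_cpgs_per_enhancer = 12)
  # pairwise disjoint: merged union length equals summed widths
  expect_equal(total_length(anno),
               sum(GenomicRanges::width(anno)))
  # every enhancer midpoint is > 2 kb from every TSS
  tss <- S4Vectors::metadata(anno)$tss
  enh <- anno[anno$element_class == "enhancer"]
  expect_true(all(assign_region_class(enh, tss) == "enhancer"))
  # elements fit on the declared chromosome
  expect_lte(max(GenomicRanges::end(anno)),
             S4Vectors::metadata(anno)$chrom_length)
  # every enhancer has >= 12 CpGs strictly inside its interval
  sites <- S4Vectors::metadata(anno)$cpg_sites
  per_enh <- table(sites$element[sites$element_class == "enhancer"])
  expect_true(all(per_enh >= 12))
  cpg_gr <- gr0("chrS", sites$pos, sites$pos + 1)
  hit <- GenomicRanges::findOverlaps(cpg_gr, anno)
  expect_equal(anno$name[S4Vectors::subjectHits(hit)], sites$element)

  expect_error(make_annotation(10, 50, chrom_length = 1000), "capacity")
  expect_error(make_annotation(0, 5), ">= 1")
})

test_that("planted direction proportions follow frac_hypo_among_dm", {
  set.seed(30)
  truth <- enhmeth:::.plant_effects(sprintf("e%05d", 1:10000), 0.5,
                                    0.955, 0.15)
  expect_equal(sum(truth$planted), 5000)
  hypo <- mean(truth$direction[truth$planted] == "hypo")
  se <- sqrt(0.955 * 0.045 / 5000)
  expect_lt(abs(hypo - 0.955), 4 * se)
  expect_true(all(truth$delta[truth$planted &
                                truth$direction == "hypo"] == -0.15))
  expect_true(all(truth$delta[!truth$planted] == 0))
})

test_that("simulated betas sit on the planted baselines within noise", {
  anno <- make_annotation(10, 60, seed = 3)
  # null cohort: no planted regions, paired difference centred on zero
  cfg0 <- effect_config(seed = 31L, n_pairs = 10L, frac_dm_regions = 0)
  m0 <- simulate_methylomes(anno, cfg0)
  d0 <- mapply(function(t, n) mean(t$beta - n$beta), m0$tumor,
               m0$non_tumor)
  se <- sd(d0) / sqrt(length(d0))
  expect_lt(abs(mean(d0)), 3 * se + 1e-3)
  # all betas valid, coverage positive
  expect_true(all(m0$tumor[[1]]$beta >= 0 & m0$tumor[[1]]$beta <= 1))
  expect_true(all(m0$tumor[[1]]$coverage >= 1))

  # planted hypo enhancers: mean paired difference near -0.15
  cfg1 <- effect_config(seed = 32L, n_pairs = 33L, frac_dm_regions = 0.3,
                        frac_hypo_among_dm = 1, beta_noise_sd = 0.01)
  m1 <- simulate_methylomes(anno, cfg1)
  sites <- S4Vectors::metadata(anno)$cpg_sites
  planted <- m1$truth$region[m1$truth$planted]
  in_planted <- sites$element %in% planted
  dbar <- mean(vapply(seq_len(33), function(j) {
    mean(m1$tumor[[j]]$beta[in_planted] -
           m1$non_tumor[[j]]$beta[in_planted])
  }, 0))
  expect_lt(abs(dbar - (-0.15)), 0.02)
  # promoters stay near the low baseline in tumors
  in_prom <- sites$element_class == "promoter"
  expect_lt(mean(m1$tumor[[1]]$beta[in_prom]), 0.05)
})

test_that("expression couplings land at their configured correlations", {
  anno <- make_annotation(6, 12, seed = 4)
  cfg <- effect_config(seed = 41L, n_pairs = 33L, frac_dm_regions = 0.5)
  # null coupling: methylation-eRNA r not significant in most seeds
  cfg0 <- effect_config(seed = 41L, erna_coupling = 1e-12)
  set.seed(42)
  meth <- matrix(runif(33, 0.3, 0.7), 1, 33,
                 dimnames = list("e1", sprintf("s%d", 1:33)))
  nonsig <- vapply(1:20, function(i) {
    ex <- simulate_expression(meth, c(e1 = "g1"), cfg0)
    pearson_test(meth[1, ], ex$erna[1, ])$p_value > 0.05
  }, TRUE)
  expect_gte(mean(nonsig), 0.9)
  # erna_coupling -0.8 at n = 33: r within the Fisher-z band
  set.seed(43)
  rs <- vapply(1:40, function(i) {
    ex <- simulate_expression(meth, c(e1 = "g1"), cfg)
    pearson_test(meth[1, ], ex$erna[1, ])$r
  }, 0)
  expect_gte(mean(rs >= -0.93 & rs <= -0.55), 0.95)
  # eRNA-mRNA coupling 0.86 at n = 808
  set.seed(44)
  meth808 <- matrix(runif(808, 0.2, 0.8), 1, 808,
                    dimnames = list("e1", sprintf("s%d", 1:808)))
  ex <- simulate_expression(meth808, c(e1 = "g1"), cfg)
  r808 <- pearson_test(ex$erna[1, ], ex$mrna[1, ])$r
  expect_lt(abs(r808 - 0.86), 0.05)
  expect_error(simulate_expression(meth, c(e1 = "g1"),
                                   effect_config(erna_coupling = 1)),
               "(-1, 1)")
})

test_that("chip tracks carry the planted enhancer-state structure", {
  anno <- make_annotation(10, 80, seed = 5)
  cfg <- effect_config(seed = 51L)
  chip <- simulate_chip_tracks(anno, cfg, seed = 51L)
  mc <- S4Vectors::mcols(chip$regions)
  # inactive enhancers sit within noise of background
  inact <- !mc$active & mc$element_class == "enhancer"
  expect_lt(median(mc$H3K27ac[inact] / mc$background[inact]), 1.5)
  # active enhancers show the signature
  act <- data.frame(H3K27ac = mc$H3K27ac, H3K4me1 = mc$H3K4me1,
                    H3K4me3 = mc$H3K4me3, H3K27me3 = mc$H3K27me3,
                    background = mc$background)
  expect_gt(mean(classify_active_enhancer(act)[mc$active]), 0.8)
  # promoters are marked by H3K4me3, not called active enhancers
  prom <- mc$element_class == "promoter"
  expect_gt(median(mc$H3K4me3[prom] / mc$background[prom]), 3)
  # planted TF/BRD4 loss fraction recovered by classify_signal_change
  tf_loss_called <-
    classify_signal_change(mc$tf_baseline, mc$tf_perturbed) == "loss" &
    classify_signal_change(mc$brd4_baseline, mc$brd4_perturbed) == "loss"
  expect_equal(sum(tf_loss_called & mc$active), sum(mc$tf_loss),
               tolerance = 0.1)
  # planted SE cluster members tower over typical enhancers
  se_members <- !is.na(mc$se_cluster)
  expect_gt(min(mc$H3K27ac[se_members]),
            max(mc$H3K27ac[mc$active & !se_members &
                             mc$element_class == "enhancer"]))
  # genes nearest K27ac-loss codepleted enhancers are down-regulated
  hit_genes <- unique(nearest_gene(chip$regions[mc$k27ac_loss],
                                   chip$tss))
  expect_lt(median(chip$expression_fc[hit_genes]), -0.5)
})

test_that("survival generator plants the configured hazard structure", {
  cfg <- effect_config(seed = 61L)
  sv <- simulate_survival(rnorm(48), cfg, seed = 61L)
  expect_equal(nrow(sv), 48)
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% 0:1))
  expect_equal(as.integer(table(sv$stratum)), c(24L, 24L))
  expect_error(simulate_survival(rnorm(10), cfg, true_hr = -1), "> 0")
  # degenerate: censor everything almost immediately -> no events ->
  # downstream log-rank refuses gracefully
  set.seed(62)
  sv0 <- simulate_survival(rnorm(10), cfg, censor_max = 1e-6)
  expect_error(logrank_test(sv0$time, sv0$event, sv0$stratum),
               "untestable")
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- effect_config(seed = 71L, n_pairs = 4L, n_genes = 5L,
                       n_enhancers = 15L, n_regions = 50L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$region_signal$counts, b$region_signal$counts)
  expect_identical(a$enh_meth, b$enh_meth)
  expect_identical(a$expression$mrna, b$expression$mrna)
  expect_identical(a$survival_os, b$survival_os)
  expect_identical(as.data.frame(a$methylomes$tumor[[1]]),
                   as.data.frame(b$methylomes$tumor[[1]]))
})
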