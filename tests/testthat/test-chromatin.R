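test_that("active-enhancer signature follows the three-mark rule with
           its boundary conventions", {
  mk <- function(k27ac, me1, me3, k27me3, bg = 1) {
    data.frame(H3K27ac = k27ac, H3K4me1 = me1, H3K4me3 = me3,
               H3K27me3 = k27me3, background = bg)
  }
  # clear active pattern: K27ac fold 5, me1/me3 ratio ~4, K27me3 fold 0.8
  expect_true(classify_active_enhancer(mk(5, 7, 1, 0.8)))
  # all marks at background -> inactive
  expect_false(classify_active_enhancer(mk(1, 1, 1, 1)))
  # boundary enumeration at the 2.0 / 2.0 / 1.5 defaults (eps = 1):
  # K27ac fold exactly 2.0 passes (>=)
  expect_true(classify_active_enhancer(mk(2, 3, 1, 0)))
  expect_false(classify_active_enhancer(mk(2 - 1e-9, 3, 1, 0)))
  # me1/me3 ratio exactly 2.0 passes (>=): (3+1)/(1+1) = 2
  expect_true(classify_active_enhancer(mk(5, 3, 1, 0)))
  expect_false(classify_active_enhancer(mk(5, 3 - 1e-6, 1, 0)))
  # K27me3 fold exactly 1.5 fails (<)
  expect_false(classify_active_enhancer(mk(5, 7, 1, 1.5)))
  expect_true(classify_active_enhancer(mk(5, 7, 1, 1.5 - 1e-9)))
  expect_error(classify_active_enhancer(mk(5, 7, 1, 0)[, -2]), "H3K4me1")
  expect_error(classify_active_enhancer(mk(1, 1, 1, 1, bg = 0)),
               "background")
})

test_that("promoter/enhancer partition uses the inclusive 2-kb midpoint
           window", {
  tss <- data.frame(gene = "g", chrom = "chrT", pos = 10000)
  # 0-based [mid-51, mid+50) -> 1-based [mid-50, mid+50], midpoint = mid
  at <- function(mid) gr0("chrT", mid - 51, mid + 50)
  expect_equal(assign_region_class(at(10000), tss), "promoter")
  expect_equal(assign_region_class(at(12000), tss), "promoter")
  expect_equal(assign_region_class(at(12001), tss), "enhancer")
  expect_equal(assign_region_class(at(100000), tss), "enhancer")
})

test_that("signal-change classification obeys the strict <1/2x and >2x
           cutoffs", {
  # exhaustive boundary enumeration around both thresholds (eps = 1)
  base <- 9  # base + eps = 10
  ratio_to_pert <- function(r) r * (base + 1) - 1
  cases <- c(0.49, 0.5, 0.51, 1, 1.99, 2, 2.01)
  got <- classify_signal_change(rep(base, length(cases)),
                                ratio_to_pert(cases))
  expect_equal(got, c("loss", "stable", "stable", "stable", "stable",
                      "stable", "gain"))
  expect_error(classify_signal_change(-1, 1), "non-negative")
  # reciprocal consistency: swapping conditions maps loss <-> gain
  set.seed(12)
  b <- runif(200, 0, 20); p <- runif(200, 0, 20)
  fwd <- classify_signal_change(b, p)
  rev <- classify_signal_change(p, b)
  expect_true(all(rev[fwd == "loss"] == "gain"))
  expect_true(all(rev[fwd == "gain"] == "loss"))
})

test_that("Yates chi-square matches the closed formula and
           stats::chisq.test", {
  flat <- chi_square_yates(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  tab <- matrix(c(20, 5, 10, 25), 2)  # [[20,10],[5,25]] column-filled
  got <- chi_square_yates(tab)
  a <- 20; b <- 10; c_ <- 5; d <- 25; N <- 60
  direct <- N * (abs(a * d - b * c_) - N / 2)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(got$statistic, direct, tolerance = 1e-10)
  ref <- chisq.test(tab, correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # clamp: weak association where |ad-bc| <= N/2 gives exactly 0
  expect_equal(chi_square_yates(matrix(c(6, 5, 5, 6), 2))$statistic, 0)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 6), 2)), "margin")
  # random tables agree with chisq.test
  set.seed(13)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi_square_yates(t2)$p_value,
                 chisq.test(t2, correct = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("super-enhancer caller stitches, ranks and cuts at the
           slope-1 point", {
  # 90 typical + 10 planted high-signal peaks, all isolated (>stitch apart)
  mk_peaks <- function(sig) {
    n <- length(sig)
    data.frame(chrom = "chrT", start = (0:(n - 1)) * 20000,
               end = (0:(n - 1)) * 20000 + 1000, signal = sig,
               background = 0)
  }
  set.seed(14)
  sig <- c(rep(1, 90), rep(50, 10))[sample(100)]
  ses <- call_super_enhancers(mk_peaks(sig))
  expect_equal(sum(ses$is_super), 10)
  expect_true(all(ses$total_signal[ses$is_super] == 50))
  # input order invariance
  ses2 <- call_super_enhancers(mk_peaks(rev(sig)))
  expect_equal(sum(ses2$is_super), 10)
  expect_equal(sort(ses$total_signal), sort(ses2$total_signal))
  # all-equal signal: scaled curve is the diagonal, nothing called
  expect_equal(sum(call_super_enhancers(mk_peaks(rep(3, 20)))$is_super), 0)
  # two peaks 5 kb apart are stitched (5,000 < 12,500); signal conserved
  close_pk <- data.frame(chrom = "chrT",
                         start = c(0, 6000, 100000, 200000),
                         end = c(1000, 7000, 101000, 201000),
                         signal = c(2, 3, 1, 1), background = 0)
  st <- call_super_enhancers(close_pk)
  expect_equal(nrow(st), 3)
  expect_equal(max(st$n_constituents), 2)
  expect_equal(sum(st$total_signal), sum(close_pk$signal))
  # a gap beyond the stitch distance stays split
  far <- close_pk; far$start[2] <- 14000; far$end[2] <- 15000
  expect_equal(nrow(call_super_enhancers(far)), 4)
  # TSS exclusion drops promoter-proximal peaks first
  tss <- data.frame(gene = "g", chrom = "chrT", pos = 500)
  st2 <- call_super_enhancers(close_pk, tss = tss)
  expect_equal(nrow(st2), 3)  # first peak near TSS removed, rest isolated
  expect_error(call_super_enhancers(close_pk[1:2, ]), "3")
})

test_that("codepletion requires loss of both factors and recovers the
           planted expression contrast", {
  set.seed(15)
  n <- 300
  tss <- data.frame(gene = sprintf("g%03d", 1:n), chrom = "chrT",
                    pos = (1:n) * 10000)
  regions <- gr0("chrT", (1:n) * 10000 + 4000, (1:n) * 10000 + 5000)
  # plant: 200 codepleted (120 with K27ac loss), 50 TF-only, 50 untouched
  codep <- 1:200; k27 <- 1:120; tf_only <- 201:250
  base <- rep(10, n)
  tf_p <- base * 0.9; tf_p[c(codep, tf_only)] <- base[1] * 0.2
  brd_p <- base * 0.9; brd_p[codep] <- base[1] * 0.2
  k27_p <- base * 0.9; k27_p[k27] <- base[1] * 0.25
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    tf_baseline = base, tf_perturbed = tf_p, brd4_baseline = base,
    brd4_perturbed = brd_p, k27ac_baseline = base, k27ac_perturbed = k27_p)
  fc <- setNames(rnorm(n, 0, 0.2), tss$gene)
  fc[tss$gene[k27]] <- rnorm(120, -1.5, 0.2)
  res <- codepletion_and_expression(regions, fc, tss)
  expect_equal(sum(res$table$codepleted), 200)
  # a region losing TF but not BRD4 is not codepleted
  expect_false(any(res$table$codepleted[tf_only]))
  expect_lt(res$median_with_loss, res$median_without_loss)
  expect_lt(res$rank_sum_p, 0.05)
  expect_equal(res$frac_reduced, mean(tf_p < base & brd_p < base))
  # empty sub-group -> warning, NA p
  all_loss <- regions[1:120]
  expect_warning(res2 <- codepletion_and_expression(all_loss, fc, tss),
                 "empty")
  expect_true(is.na(res2$rank_sum_p))
})
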