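test_that("pyro percent methylation follows M/(M+U) and is
           scale-invariant", {
  expect_equal(pyro_methylation_percent(100, 0)$per_cpg, 100)
  expect_equal(pyro_methylation_percent(7, 7)$per_cpg, 50)

  set.seed(3)
  m <- runif(13, 1, 100); u <- runif(13, 1, 100)
  res <- pyro_methylation_percent(m, u)
  expect_equal(res$per_cpg, 100 * m / (m + u))
  expect_equal(res$mean, mean(100 * m / (m + u)))
  for (k in runif(20, 0.01, 50)) {
    expect_equal(pyro_methylation_percent(k * m, k * u)$per_cpg,
                 res$per_cpg)
  }
  # zero-signal CpG excluded from the mean; conversion control flags
  res0 <- pyro_methylation_percent(c(10, 0), c(10, 0))
  expect_true(is.na(res0$per_cpg[2]))
  expect_equal(res0$mean, 50)
  expect_false(pyro_methylation_percent(1, 1,
                                        control_signal = 50)$conversion_ok)
  # ratio reading exceeds 100% when M > U
  expect_equal(pyro_methylation_percent(20, 10,
                                        mode = "ratio")$per_cpg, 200)
})

test_that("2^-ddCt folds behave as closed forms and resist common Ct
           shifts", {
  rec <- data.frame(sample = c("r1", "r2", "t1", "t2"),
                    group = c("reference", "reference",
                              "treatment", "treatment"),
                    ct_target = c(20, 21, 18.5, 22.5),
                    ct_control = c(15, 16, 15.5, 17.5))
  out <- ddct_fold_change(rec)
  # reference mean dCt = 5; treatment dCt = 3 -> fold 4; dCt = 5 -> fold 1
  expect_equal(out$fold[3], 4)
  expect_equal(out$fold[4], 1)
  expect_equal(mean(out$ddct[out$group == "reference"]), 0)

  set.seed(9)
  for (shift in rnorm(25, 0, 10)) {
    shifted <- rec
    shifted$ct_target <- rec$ct_target + shift
    shifted$ct_control <- rec$ct_control + shift
    expect_equal(ddct_fold_change(shifted)$fold, out$fold)
  }
  expect_error(ddct_fold_change(rec, reference = "missing"),
               "reference group")
})

test_that("pearson_test matches the covariance formula and cor.test", {
  x <- 1:8
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    got <- pearson_test(x, y)
    r_direct <- cov(x, y) / (sd(x) * sd(y))
    expect_equal(got$r, r_direct, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
    less <- pearson_test(x, y, alternative = "less")
    expect_equal(less$p_value,
                 cor.test(x, y, alternative = "less")$p.value,
                 tolerance = 1e-10)
  }
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("signed-rank test reproduces exhaustive enumeration and the
           large-n normal approximation", {
  set.seed(4)
  for (i in 1:8) {
    d <- round(rnorm(8, 0.3), 2)
    d <- d[d != 0]
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, brute_signed_rank_p(d))
    if (!any(duplicated(abs(d)))) {
      ref <- wilcox.test(d, exact = TRUE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value)
    }
  }
  # symmetric +/- pairs of equal magnitude sit in the middle of the null
  expect_gt(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p_value, 0.9)
  # above the exact cutoff: continuity-corrected normal vs wilcox.test
  set.seed(5)
  d <- rnorm(33, 0.4)
  got <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_equal(got$method, "normal_approx")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # p decreases monotonically with a uniform shift
  set.seed(6)
  base <- rnorm(33)
  ps <- vapply(c(0, 0.3, 0.6, 1), function(s) {
    wilcoxon_signed_rank(base + s)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(wilcoxon_signed_rank(c(0, 0)), "untestable")
})

test_that("t statistics match the closed forms and stats::t.test", {
  x <- c(1, 2, 3, 4)
  same <- t_tests(x, x + rnorm(4, 0, 1e-12))
  expect_equal(same$statistic, 0, tolerance = 1e-3)
  set.seed(8)
  for (i in 1:6) {
    x <- rnorm(7); y <- rnorm(9, 0.5)
    got <- t_tests(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    xp <- rnorm(8); yp <- rnorm(8)
    gp <- t_tests(xp, yp, paired = TRUE)
    rp <- t.test(xp, yp, paired = TRUE)
    expect_equal(gp$statistic, unname(rp$statistic), tolerance = 1e-10)
    expect_equal(gp$p_value, rp$p.value, tolerance = 1e-10)
  }
  # noise-free paired shift: overflow-safe extreme
  deg <- t_tests(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_true(is.infinite(deg$statistic))
  expect_equal(deg$p_value, 0)
  expect_error(t_tests(c(1, 1), c(1, 1)), "untestable")
  # one-tailed halves the two-sided p
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(t_tests(x, y, two_tailed = FALSE)$p_value,
               t_tests(x, y)$p_value / 2)
})
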