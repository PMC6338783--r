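#' Pyrosequencing percent methylation
#'
#' Converts per-CpG methylated (M) and unmethylated (U) pyrosequencing
#' signals into percent methylation. The default reading is the standard
#' proportion 100 * M / (M + U); the raw M / U ratio reading is available
#' behind `mode = "ratio"` for auditability (it can exceed 100%).
#' Non-CpG cytosine signal serves as a bisulfite-conversion control: any
#' control signal above `control_tol` flags the assay as failed.
#'
#' @param m,u Numeric vectors of methylated / unmethylated signal per CpG.
#' @param control_signal Optional numeric vector of non-CpG cytosine signal.
#' @param control_tol Tolerance above which conversion is deemed incomplete.
#' @param mode `"proportion"` (default) or `"ratio"`.
#' @return List with `per_cpg` percent values (NA where M + U = 0),
#'   `mean` over reportable CpGs, and `conversion_ok`.
#' @examples
#' pyro_methylation_percent(c(40, 55), c(60, 45))
#' @export
pyro_methylation_percent <- function(m, u, control_signal = NULL,
                                     control_tol = 5,
                                     mode = c("proportion", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(m) == length(u))
  if (any(m < 0 | u < 0)) stop("pyrosequencing signals must be >= 0")
  tot <- m + u
  pct <- rep(NA_real_, length(m))
  ok <- tot > 0
  pct[ok] <- if (mode == "proportion") 100 * m[ok] / tot[ok] else
    100 * m[ok] / u[ok]
  conversion_ok <- is.null(control_signal) ||
    all(control_signal <= control_tol)
  list(per_cpg = pct, mean = mean(pct, na.rm = TRUE),
       conversion_ok = conversion_ok)
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample fold changes relative to a reference group using an
#' internal-control gene (e.g. 18S rRNA): dCt = Ct(target) - Ct(control),
#' ddCt = dCt - mean(dCt of reference group), fold = 2^-ddCt. The
#' reference-group geometric mean fold is 1 by construction, and folds are
#' invariant under any common additive shift applied to every Ct.
#'
#' @param records Data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_control`.
#' @param reference Name of the reference group (default `"reference"`).
#' @return `records` with added columns `dct`, `ddct`, `fold`.
#' @export
ddct_fold_change <- function(records, reference = "reference") {
  stopifnot(all(c("sample", "group", "ct_target", "ct_control") %in%
                  names(records)))
  if (!any(records$group == reference)) {
    stop("no samples in reference group '", reference, "'")
  }
  if (!all(is.finite(records$ct_target)) ||
      !all(is.finite(records$ct_control))) {
    stop("Ct values must be finite")
  }
  records$dct <- records$ct_target - records$ct_control
  ref_mean <- mean(records$dct[records$group == reference])
  records$ddct <- records$dct - ref_mean
  records$fold <- 2^(-records$ddct)
  records
}

#' Pearson correlation with t-based p-value
#'
#' Textbook product-moment correlation with a two-sided (default) p-value
#' from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @param alternative `"two.sided"`, `"less"` (r < 0) or `"greater"`.
#' @return List with `r`, `p_value`, `n`, `statistic` (t).
#' @export
pearson_test <- function(x, y,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2L
  tstat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE))
  list(r = r, p_value = min(1, p), n = n, statistic = tstat)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; ties get mid-ranks. For n <= `exact_max`
#' retained differences the two-sided p-value comes from exact enumeration
#' of all 2^n sign assignments of the (mid-)ranks; above that, a normal
#' approximation with continuity correction and the usual tie correction of
#' the null variance is used.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact null is enumerated.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n` (non-zero differences used), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 12L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("untestable: all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(wdist <= W), mean(wdist >= W)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = min(1, p), n = n, method = method)
}

#' Student's t-tests (paired and unpaired pooled-variance)
#'
#' Standard t statistics with closed-form handling of the noise-free paired
#' degenerate case (constant non-zero differences give t = +/-Inf, p = 0).
#'
#' @param x,y Numeric vectors (equal length when `paired = TRUE`).
#' @param paired Paired test on x - y?
#' @param two_tailed Two-sided p-value? One-tailed halves the two-sided p
#'   in the direction of the observed statistic.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
t_tests <- function(x, y, paired = FALSE, two_tailed = TRUE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    n <- length(d)
    if (n < 2L) stop("need at least 2 pairs")
    s <- stats::sd(d)
    if (s == 0) {
      if (mean(d) == 0) stop("untestable: zero variance and zero effect")
      tstat <- sign(mean(d)) * Inf
      df <- n - 1L
      p <- 0
    } else {
      tstat <- mean(d) / (s / sqrt(n))
      df <- n - 1L
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  } else {
    nx <- length(x); ny <- length(y)
    if (nx < 2L || ny < 2L) stop("need at least 2 observations per group")
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
      if (mean(x) == mean(y)) stop("untestable: zero variance in both groups")
      tstat <- sign(mean(x) - mean(y)) * Inf
      df <- nx + ny - 2L
      p <- 0
    } else {
      sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
      tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
      df <- nx + ny - 2L
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  if (!two_tailed) p <- p / 2
  list(statistic = tstat, df = df, p_value = p)
}
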