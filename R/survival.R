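#' Stratify patients by relative enhancer hypomethylation
#'
#' Patients are ranked by relative methylation (tumor minus matched
#' non-tumor; more negative = stronger hypomethylation) ascending; the
#' lower half is the strong-hypomethylation stratum. With odd n the median
#' patient goes to the weak stratum, and exact ties are broken by stable
#' input order.
#'
#' @param relative_methylation Numeric vector, one value per patient.
#' @return Factor with levels `strong_hypo`, `weak_hypo`, aligned with the
#'   input order.
#' @export
stratify_by_hypomethylation <- function(relative_methylation) {
  n <- length(relative_methylation)
  if (n < 2L) stop("need at least 2 patients")
  ord <- order(relative_methylation)  # stable for ties
  stratum <- rep("weak_hypo", n)
  stratum[ord[seq_len(n %/% 2L)]] <- "strong_hypo"
  factor(stratum, levels = c("strong_hypo", "weak_hypo"))
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Data.frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (right-continuous step values).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank (Mantel-Cox) test between hypomethylation strata
#'
#' Compares the survival distributions of the two strata with the
#' Mantel-Cox log-rank test and reports the observed/expected hazard-ratio
#' estimator HR = (O1/E1)/(O2/E2) with the strong-hypomethylation stratum
#' as group 1.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param stratum Factor from [stratify_by_hypomethylation()] (or any
#'   two-level factor; the first level is group 1).
#' @return List with `statistic` (chi-square, 1 df), `p_value`,
#'   `hazard_ratio`, `obs`, `exp`.
#' @export
logrank_test <- function(time, event, stratum) {
  stopifnot(length(time) == length(event), length(time) == length(stratum))
  if (any(time <= 0)) stop("times must be positive")
  stratum <- droplevels(as.factor(stratum))
  if (nlevels(stratum) != 2L) stop("need exactly 2 non-empty strata")
  if (sum(event) == 0) stop("untestable: no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum)
  # survdiff orders groups by factor level; level 1 is group 1
  obs <- as.numeric(sd$obs); expd <- as.numeric(sd$exp)
  hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
  list(statistic = as.numeric(sd$chisq),
       p_value = stats::pchisq(as.numeric(sd$chisq), df = 1,
                               lower.tail = FALSE),
       hazard_ratio = hr, obs = obs, exp = expd)
}
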