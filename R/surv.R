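#' Kaplan-Meier recurrence-free-survival estimate
#'
#' Product-limit estimator of the survival function (backed by
#' `survival::survfit`): `S(0) = 1`, nonincreasing, with censored subjects
#' leaving the risk set without contributing an event.
#'
#' @param time follow-up times (months), >= 0.
#' @param event logical/0-1 event indicator (recurrence).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (one row per
#'   distinct observed time).
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank comparison of recurrence-free survival
#' between predicted responders and non-responders (backed by
#' `survival::survdiff`): observed vs expected events per group summed
#' over event times, with the hypergeometric variance handling ties;
#' p-value from the chi-square(1) tail.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group two-level grouping vector.
#' @return list with `chisq` and `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("log-rank comparison needs exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  list(chisq = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Right-tailed unpaired t-test
#'
#' Student's pooled-variance unpaired t-test of H1: mean(A) > mean(B),
#' used for per-parameter responder vs non-responder comparisons (Welch's
#' version behind a flag).
#'
#' @param a,b numeric samples.
#' @param pooled use the pooled-variance Student test (default TRUE);
#'   FALSE gives Welch.
#' @return one-sided p-value `P(T > t)`.
#' @export
ttest_right <- function(a, b, pooled = TRUE) {
  stats::t.test(a, b, alternative = "greater", var.equal = pooled)$p.value
}

#' Simulate recurrence-free-survival data for two response groups
#'
#' Exponential event times with the non-responder hazard scaled by
#' `1 / hazard_ratio` relative to responders, and independent uniform
#' censoring; used by the synthetic cohort.
#'
#' @param n_responders,n_non_responders group sizes.
#' @param hazard_ratio responder/non-responder hazard ratio (< 1 means
#'   responders recur more slowly).
#' @param base_rate responder event rate per month.
#' @param censor_max months; censoring times are Uniform(0, censor_max).
#' @param seed integer.
#' @return data.frame with `patient_id`, `group`, `time`, `event`.
#' @export
simulate_survival <- function(n_responders, n_non_responders,
                              hazard_ratio = 0.3, base_rate = 0.01,
                              censor_max = 60, seed = 1) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  set.seed(seed)
  n <- n_responders + n_non_responders
  group <- rep(c("responder", "non-responder"),
               c(n_responders, n_non_responders))
  rate <- ifelse(group == "responder", base_rate, base_rate / hazard_ratio)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_max)
  data.frame(patient_id = seq_len(n), group = group,
             time = pmin(t_event, t_cens),
             event = t_event <= t_cens)
}
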