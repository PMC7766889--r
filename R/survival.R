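#' Dichotomize samples by signature score
#'
#' `median`: split at the median score, ties going to the low group.
#' `scan`: evaluate every distinct score (except the largest, which would
#' empty the high group) as a cutoff, pick the one minimizing the log-rank
#' p-value, and report how many cutoffs were tested — the scan p-value is
#' nominal, not corrected for this multiple testing.
#'
#' @param scores named numeric vector or [signature_score()] data.frame;
#'   at least two distinct values.
#' @param method `"median"` or `"scan"`.
#' @param time,event survival data, required for `"scan"`.
#' @return list `group` (named character, `"high"`/`"low"`), `cutoff`,
#'   `method`; for scan additionally `n_cutoffs_tested` and `p_value`
#'   (nominal) at the chosen cutoff.
#' @export
dichotomize <- function(scores, method = c("median", "scan"),
                        time = NULL, event = NULL) {
  method <- match.arg(method)
  scores <- as_score_vector(scores)
  if (length(unique(scores)) < 2) stop2("all scores equal: cannot dichotomize")
  if (method == "median") {
    cutoff <- stats::median(scores)
    group <- ifelse(scores > cutoff, "high", "low")
    names(group) <- names(scores)
    return(list(group = group, cutoff = cutoff, method = "median"))
  }
  if (is.null(time) || is.null(event)) {
    stop2("scan dichotomization needs time and event")
  }
  cand <- sort(unique(scores))
  cand <- cand[-length(cand)]
  ps <- vapply(cand, function(ct) {
    g <- ifelse(scores > ct, "high", "low")
    logrank_test(time, event, g)$p_value
  }, numeric(1))
  best <- which.min(ps)
  cutoff <- cand[best]
  group <- ifelse(scores > cutoff, "high", "low")
  names(group) <- names(scores)
  list(group = group, cutoff = cutoff, method = "scan",
       n_cutoffs_tested = length(cand), p_value = ps[best])
}

#' Kaplan-Meier product-limit estimate
#'
#' Per group, at each distinct event time `t` the survival probability is
#' multiplied by `1 - d_t / n_t` (events over number at risk); censored
#' subjects leave the risk set after their time, and at tied times events
#' precede censoring. Computed with [survival::survfit()].
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1/TRUE = death observed).
#' @param group optional group labels; single group if omitted.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, one row per distinct observed time.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0)) stop2("negative survival times")
  event <- as.integer(as.logical(event))
  if (is.null(group)) group <- rep("all", length(time))
  if (length(unique(group)) < 1 || any(table(group) < 1)) {
    stop2("each group needs at least one record")
  }
  df <- data.frame(time = time, event = event, group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(df$group), length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  data.frame(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-group log-rank test
#'
#' Standard 1-df chi-square: `(sum(O - E))^2 / sum(V)` over event times,
#' with hypergeometric expectations and variances. Computed with
#' [survival::survdiff()].
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1/TRUE = death observed).
#' @param group exactly two group labels, both non-empty.
#' @return list `statistic`, `p_value`, `n_per_group`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop2("negative survival times")
  event <- as.integer(as.logical(event))
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) != 2) stop2("log-rank test needs exactly two groups")
  if (any(tab == 0)) stop2("one group is empty")
  if (sum(event) < 1) stop2("need at least one observed event")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  statistic <- unname(sd$chisq)
  list(
    statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    n_per_group = stats::setNames(as.integer(tab), names(tab))
  )
}
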