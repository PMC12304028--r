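## Trial endpoint statistics: exact binomial intervals, asparaginase
## activity threshold attainment, Kaplan-Meier survival, response rates.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central interval from beta-distribution quantiles:
#' lower = `qbeta(a/2, k, n-k+1)` (0 when k = 0),
#' upper = `qbeta(1-a/2, k+1, n-k)` (100\% when k = n).
#'
#' @param k successes; @param n trials; @param level confidence level.
#' @return list `proportion`, `lower`, `upper` in percent (unrounded).
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("invalid k/n")
  if (level <= 0 || level >= 1) stop("invalid confidence level")
  a <- 1 - level
  lo <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  list(proportion = 100 * k / n, lower = 100 * lo, upper = 100 * hi)
}

#' Asparaginase-activity threshold attainment
#'
#' A subject attains the endpoint if the observation nearest `t_target`
#' (default 336 h = 14 days) within the acceptance window (default
#' +/-24 h) is `>= threshold` (default 0.1 IU/ml; the boundary attains).
#' BLQ records count as below threshold; records flagged in an optional
#' `EXCL` column are ignored; subjects with no in-window sample are
#' non-evaluable and excluded from `n`.
#'
#' @param data event-record dataset (TIME in h from first dose).
#' @param t_target h; @param threshold IU/ml; @param window h.
#' @param level confidence level for the Clopper-Pearson interval.
#' @return list of class `attainment_result`: `n_evaluable`,
#'   `n_attaining`, `proportion`, `ci_lower`, `ci_upper` (percent),
#'   `level`.
#' @export
threshold_attainment <- function(data, t_target = 336, threshold = 0.1,
                                 window = 24, level = 0.95) {
  n_eval <- 0L; n_att <- 0L
  for (id in unique(data$ID)) {
    d <- data[data$ID == id & data$EVID == 0, ]
    if (!is.null(d$EXCL)) d <- d[!(d$EXCL %in% 1), ]
    d <- d[abs(d$TIME - t_target) <= window, ]
    if (!nrow(d)) next
    d <- d[which.min(abs(d$TIME - t_target)), ]
    val <- if (d$BLQ == 1 || is.na(d$DV)) 0 else d$DV
    n_eval <- n_eval + 1L
    if (val >= threshold) n_att <- n_att + 1L
  }
  if (n_eval == 0) stop("endpoint error: no evaluable subjects")
  ci <- clopper_pearson(n_att, n_eval, level)
  structure(list(n_evaluable = n_eval, n_attaining = n_att,
                 proportion = ci$proportion, ci_lower = ci$lower,
                 ci_upper = ci$upper, level = level),
            class = "attainment_result")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variance (via the survival
#' package, plain/linear confidence intervals).
#'
#' @param event_times times (days); @param event_flags 1/TRUE = event,
#'   0/FALSE = censored.
#' @param horizon time at which survival is reported (default 365 d).
#' @return list of class `survival_estimate`: `time`, `surv`, `lower`,
#'   `upper`, `n_risk` (step function), and `surv_at_horizon` (percent,
#'   with CI).
#' @export
km_estimate <- function(event_times, event_flags, horizon = 365) {
  if (!length(event_times)) stop("empty input")
  sf <- survival::survfit(survival::Surv(event_times, as.integer(event_flags)) ~ 1,
                          conf.type = "plain")
  at <- summary(sf, times = min(horizon, max(event_times)), extend = TRUE)
  structure(list(time = sf$time, surv = sf$surv, lower = sf$lower,
                 upper = sf$upper, n_risk = sf$n.risk,
                 surv_at_horizon = 100 * at$surv,
                 ci_lower = 100 * at$lower, ci_upper = 100 * at$upper),
            class = "survival_estimate")
}

#' Response-rate summary (CR / CRi / ORR)
#'
#' @param labels character vector of per-subject best responses from
#'   `{"CR", "CRi", "other"}`.
#' @param level confidence level.
#' @return data frame with rows CR, CRi, ORR: rate (percent) and exact CI.
#' @export
response_summary <- function(labels, level = 0.95) {
  if (!all(labels %in% c("CR", "CRi", "other")))
    stop("unknown response label(s): ",
         paste(setdiff(labels, c("CR", "CRi", "other")), collapse = ", "))
  n <- length(labels)
  rows <- list(CR = sum(labels == "CR"), CRi = sum(labels == "CRi"),
               ORR = sum(labels %in% c("CR", "CRi")))
  out <- lapply(names(rows), function(nm) {
    ci <- clopper_pearson(rows[[nm]], n, level)
    data.frame(endpoint = nm, n = n, k = rows[[nm]], rate = ci$proportion,
               ci_lower = ci$lower, ci_upper = ci$upper)
  })
  do.call(rbind, out)
}
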