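## Non-compartmental analysis of individual activity-time profiles.

#' Trapezoidal AUC over the observed span
#'
#' `"linup-logdown"` (default) uses the linear trapezoid on rising or flat
#' segments and the log trapezoid \eqn{(C_1-C_2)\Delta t/\ln(C_1/C_2)} on
#' strictly decreasing segments with both endpoints positive; `"linear"`
#' uses the linear rule throughout.
#'
#' @param times strictly increasing times (h).
#' @param activities activities (IU/ml), `>= 0`.
#' @param method `"linup-logdown"` or `"linear"`.
#' @param moment if `TRUE`, integrate `t * C(t)` (AUMC) under the same
#'   segment rules (exponential segment assumption for log-down).
#' @return AUC (h.IU/ml), partial over `[times[1], times[n]]`.
#' @export
auc_trapezoid <- function(times, activities, method = c("linup-logdown", "linear"),
                          moment = FALSE) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2) stop("insufficient data: need at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(activities < 0)) stop("activities must be non-negative")
  total <- 0
  for (i in seq_len(n - 1)) {
    t1 <- times[i]; t2 <- times[i + 1]; c1 <- activities[i]; c2 <- activities[i + 1]
    dt <- t2 - t1
    logdown <- method == "linup-logdown" && c2 < c1 && c2 > 0
    if (!moment) {
      total <- total + if (logdown) (c1 - c2) * dt / log(c1 / c2)
                       else dt * (c1 + c2) / 2
    } else {
      if (logdown) {
        lam <- log(c1 / c2) / dt
        total <- total + (t1 * c1 - t2 * c2) / lam + (c1 - c2) / lam^2
      } else total <- total + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  total
}

#' Terminal slope by best-adjusted-R-squared log-linear regression
#'
#' Regresses `log(C)` on `t` over candidate windows of at least
#' `min_points` points ending at the last positive observation, excluding
#' the Cmax point itself (IV profiles); picks the window maximising
#' adjusted R^2, ties broken toward more points.
#'
#' @param times,activities profile (post-dose); non-positive activities are
#'   ignored.
#' @param min_points minimum window size (default 3).
#' @return list `lambda_z` (1/h), `adj_r2`, `n_points`, `t_first` (window
#'   start time).
#' @export
fit_lambda_z <- function(times, activities, min_points = 3) {
  keep <- activities > 0
  times <- times[keep]; activities <- activities[keep]
  imax <- which.max(activities)[1]
  ## candidate points: strictly after Cmax
  ct <- times[-seq_len(imax)]; cc <- activities[-seq_len(imax)]
  if (length(ct) < min_points)
    stop("insufficient data: fewer than ", min_points, " post-peak points")
  best <- NULL
  ly <- log(cc)
  for (start in seq_len(length(ct) - min_points + 1)) {
    tt <- ct[start:length(ct)]; yy <- ly[start:length(ct)]
    np <- length(tt)
    tc <- tt - mean(tt); yc <- yy - mean(yy)
    slope <- sum(tc * yc) / sum(tc^2)
    if (!is.finite(slope) || slope >= 0) next
    sse <- sum((yc - slope * tc)^2)
    sst <- sum(yc^2)
    r2 <- if (sst <= 0) 1 else 1 - sse / sst
    ar2 <- 1 - (1 - r2) * (np - 1) / (np - 2)
    if (is.null(best) || ar2 > best$adj_r2 + 1e-12) ## ties -> more points (earlier start)
      best <- list(lambda_z = -slope, adj_r2 = ar2,
                   n_points = np, t_first = tt[1])
  }
  if (is.null(best)) stop("lambda-estimation error: no decaying terminal phase")
  best
}

#' Non-compartmental analysis of one profile
#'
#' Cmax/tmax from the observed points (ties to the earliest time);
#' `AUC0_inf = AUC0_t + C_last/lambda_z`; `CL = dose/AUC0_inf`;
#' `MRT = AUMC0_inf/AUC0_inf - TI/2` (infusion-duration correction);
#' `Vss = CL * MRT`; `t_half = ln 2 / lambda_z`. BLQ values after the last
#' positive observation are excluded; a leading zero anchors the AUC.
#'
#' @param times,activities observed profile (h, IU/ml) from dose start.
#' @param dose administered amount (IU).
#' @param infusion_duration h.
#' @param method AUC method, see [auc_trapezoid()].
#' @return list of class `nca_result`: `Cmax`, `tmax`, `AUC0_t`,
#'   `AUC0_inf`, `lambda_z`, `t_half`, `CL`, `Vss`, `pct_extrapolated`,
#'   `n_lambda_points`, `adj_r2`.
#' @export
compute_nca <- function(times, activities, dose, infusion_duration = 2,
                        method = "linup-logdown") {
  stopifnot(dose > 0, length(times) == length(activities))
  ord <- order(times)
  times <- times[ord]; activities <- activities[ord]
  last_pos <- max(which(activities > 0))
  times <- times[seq_len(last_pos)]; activities <- activities[seq_len(last_pos)]
  Cmax <- max(activities); tmax <- times[which.max(activities)[1]]
  lz <- fit_lambda_z(times, activities)
  auc_t <- auc_trapezoid(times, activities, method)
  aumc_t <- auc_trapezoid(times, activities, method, moment = TRUE)
  c_last <- activities[length(activities)]; t_last <- times[length(times)]
  auc_inf <- auc_t + c_last / lz$lambda_z
  aumc_inf <- aumc_t + c_last * t_last / lz$lambda_z + c_last / lz$lambda_z^2
  pct_extra <- 100 * (1 - auc_t / auc_inf)
  if (pct_extra > 20)
    warning(sprintf("AUC extrapolation %.1f%% exceeds 20%%", pct_extra))
  CL <- dose / (auc_inf * 1000)          # activity in IU/ml -> AUC in h*IU/ml
  mrt <- aumc_inf / auc_inf - infusion_duration / 2
  structure(list(Cmax = Cmax, tmax = tmax, AUC0_t = auc_t, AUC0_inf = auc_inf,
                 lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
                 CL = CL, Vss = CL * mrt, pct_extrapolated = pct_extra,
                 n_lambda_points = lz$n_points, adj_r2 = lz$adj_r2),
            class = "nca_result")
}

#' Per-subject NCA over an event-record dataset
#'
#' Runs [compute_nca()] on each subject's first-dose profile (observations
#' before the second dose), using the recorded dose amount and infusion
#' duration. BLQ observations are treated as zero anchors before the first
#' positive value and dropped after the last positive value.
#'
#' @param data event-record data frame.
#' @return data frame, one row per evaluable subject, with the NCA fields
#'   plus `ID`, `BSA`, `dose` and the dosing-threshold group
#'   (`"BSA>=0.6"` / `"BSA<0.6"`).
#' @export
nca_by_subject <- function(data) {
  out <- list()
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, ]
    dose_rows <- d[d$EVID == 1, ]
    if (!nrow(dose_rows)) next
    t2 <- if (nrow(dose_rows) > 1) dose_rows$TIME[2] else Inf
    obs <- d[d$EVID == 0 & d$TIME < t2, ]
    tt <- obs$TIME - dose_rows$TIME[1]
    yy <- ifelse(obs$BLQ == 1 | is.na(obs$DV), 0, obs$DV)
    res <- tryCatch(compute_nca(tt, yy, dose_rows$AMT[1], dose_rows$DUR[1]),
                    error = function(e) NULL)
    if (is.null(res)) next
    out[[length(out) + 1]] <- data.frame(ID = id, BSA = d$BSA[1],
      group = ifelse(d$BSA[1] >= 0.6, "BSA>=0.6", "BSA<0.6"),
      dose = dose_rows$AMT[1], as.data.frame(unclass(res)))
  }
  do.call(rbind, out)
}

#' Dose-group NCA summary
#'
#' Summarises per-subject NCA results by BSA dosing threshold in the layout
#' of a trial PK summary table: arithmetic mean (SD) for Cmax, AUCs, t1/2,
#' CL and Vss, median (range) for tmax.
#'
#' @param nca_tab output of [nca_by_subject()].
#' @return data frame with one row per group and parameter.
#' @export
nca_group_summary <- function(nca_tab) {
  pars <- c("Cmax", "AUC0_t", "AUC0_inf", "t_half", "CL", "Vss")
  out <- list()
  for (g in unique(nca_tab$group)) {
    sub <- nca_tab[nca_tab$group == g, ]
    for (p in pars)
      out[[length(out) + 1]] <- data.frame(group = g, parameter = p, n = nrow(sub),
        mean = mean(sub[[p]]), sd = sd(sub[[p]]), median = median(sub[[p]]),
        min = min(sub[[p]]), max = max(sub[[p]]))
    out[[length(out) + 1]] <- data.frame(group = g, parameter = "tmax", n = nrow(sub),
      mean = mean(sub$tmax), sd = sd(sub$tmax), median = median(sub$tmax),
      min = min(sub$tmax), max = max(sub$tmax))
  }
  do.call(rbind, out)
}
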