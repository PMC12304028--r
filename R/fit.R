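## Maximum-likelihood population fit over the FOCEI objective, with
## log/bounded transforms for positivity, a central-difference numerical
## Hessian for the variance-covariance matrix, stepwise covariate model
## building, and visual predictive checks.

## packing spec: data.frame(name, type, key)
.build_pspec <- function(model, est_theta, est_omega, est_sigma) {
  ps <- list()
  for (p in est_theta)
    ps[[length(ps) + 1]] <- data.frame(name = paste0("theta_", p),
                                       type = "log_theta", key = p)
  ce <- model$covariates
  if (nrow(ce) && !is.null(ce$fixed)) {
    for (i in which(!ce$fixed))
      ps[[length(ps) + 1]] <- data.frame(
        name = paste0("beta_", ce$param[i], "_", ce$cov[i]),
        type = "cov", key = as.character(i))
  }
  for (p in est_omega)
    ps[[length(ps) + 1]] <- data.frame(name = paste0("omega_", p),
                                       type = "log_om_sd", key = p)
  for (p in est_sigma)
    ps[[length(ps) + 1]] <- data.frame(name = paste0("sigma_", p),
                                       type = "log_sigma", key = p)
  do.call(rbind, ps)
}

.pack <- function(model, pspec) {
  x <- numeric(nrow(pspec))
  for (i in seq_len(nrow(pspec))) {
    k <- pspec$key[i]
    x[i] <- switch(pspec$type[i],
      log_theta = log(model$theta[k]),
      cov = model$covariates$value[as.integer(k)],
      log_om_sd = log(sqrt(model$omega[k])),
      log_sigma = log(model$sigma[k]))
  }
  setNames(x, pspec$name)
}

.unpack <- function(x, model, pspec) {
  for (i in seq_len(nrow(pspec))) {
    k <- pspec$key[i]
    switch(pspec$type[i],
      log_theta = { model$theta[k] <- exp(x[i]) },
      cov = { model$covariates$value[as.integer(k)] <- x[i] },
      log_om_sd = { model$omega[k] <- exp(x[i])^2 },
      log_sigma = { model$sigma[k] <- exp(x[i]) })
  }
  model
}

.num_hessian <- function(fn, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      xp <- x; xp[i] <- x[i] + h; xm <- x; xm[i] <- x[i] - h
      H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
    } else {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
      xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
      xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
      H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
    }
  }
  H
}

#' Fit a population model by FOCEI
#'
#' Minimises the FOCEI objective over the fixed effects (log scale),
#' covariate-effect coefficients (fractional shifts bounded below at
#' -0.95), between-subject standard deviations and residual parameters
#' (log scale), so positivity and a positive semi-definite (diagonal)
#' Omega hold by construction. The variance-covariance matrix of the
#' estimates is obtained from the inverse numerical Hessian of the
#' objective at the optimum (`vcov = 2 H^{-1}` since the objective is
#' -2 log-likelihood); relative standard errors are reported per
#' parameter.
#'
#' @param data event-record dataset.
#' @param model starting `pk_model`; covariate rows carrying
#'   `fixed = FALSE` are estimated.
#' @param est_theta names of typical values to estimate (default `CL`,
#'   `Vc`).
#' @param est_omega names of omega entries to estimate (default: the
#'   positive ones).
#' @param est_sigma residual components to estimate (default `"prop"`).
#' @param blq BLQ policy passed to the objective.
#' @param hessian compute the covariance matrix of estimates?
#' @param control passed to [stats::nlminb()].
#' @return object of class `pk_fit` (a `pk_model` plus `ofv`, `vcov` on
#'   the estimation scale, `par`, `pspec`, `rse`, `convergence`).
#' @export
fit_population <- function(data, model, est_theta = c("CL", "Vc"),
                           est_omega = names(model$omega)[model$omega > 0],
                           est_sigma = "prop", blq = "m1",
                           hessian = TRUE,
                           control = list(rel.tol = 1e-9, iter.max = 400,
                                          eval.max = 600)) {
  subs <- .prep_subjects(data, blq)
  if (is.null(model$covariates$fixed) && nrow(model$covariates))
    model$covariates$fixed <- TRUE
  pspec <- .build_pspec(model, est_theta, est_omega, est_sigma)
  x0 <- .pack(model, pspec)
  warm <- new.env()
  obj <- function(x) {
    m <- .unpack(x, model, pspec)
    val <- tryCatch(.foce_ofv_subs(subs, m, warm), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  lower <- ifelse(pspec$type == "cov", -0.95, -Inf)
  upper <- ifelse(pspec$type == "cov", 20, Inf)
  opt <- nlminb(x0, obj, lower = lower, upper = upper, control = control)
  if (opt$convergence != 0 && !grepl("relative convergence|both X|singular",
                                     tolower(opt$message %||% "")))
    warning("fit did not report clean convergence: ", opt$message)
  fit <- .unpack(opt$par, model, pspec)
  fit$ofv <- opt$objective
  fit$par <- setNames(opt$par, pspec$name)
  fit$pspec <- pspec
  fit$convergence <- opt$convergence
  fit$vcov <- NULL
  if (hessian) {
    H <- .num_hessian(obj, opt$par)
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      dimnames(vc) <- list(pspec$name, pspec$name)
      fit$vcov <- vc
      se <- sqrt(diag(vc))
      ## on the log scale, SE(log x) is approximately the RSE of x
      fit$rse <- setNames(100 * ifelse(pspec$type == "cov",
                                       abs(se / opt$par), se), pspec$name)
    }
  }
  class(fit) <- c("pk_fit", "pk_model")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_fit <- function(x, ...) {
  cat("FOCEI population fit: OFV =", format(x$ofv, digits = 8), "\n")
  est <- vapply(seq_len(nrow(x$pspec)), function(i) {
    k <- x$pspec$key[i]
    switch(x$pspec$type[i],
           log_theta = x$theta[[k]], cov = x$covariates$value[as.integer(k)],
           log_om_sd = sqrt(x$omega[[k]]), log_sigma = x$sigma[[k]])
  }, 0)
  tab <- data.frame(parameter = x$pspec$name, estimate = signif(est, 4))
  if (!is.null(x$rse)) tab$rse_pct <- signif(x$rse, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

## ---- stepwise covariate model building ------------------------------------

#' Stepwise covariate model building with adaptive scope reduction
#'
#' Forward inclusion adds, one at a time, the candidate with the largest
#' objective drop if it exceeds `forward` (default 3.84, p < 0.05, 1 df);
#' backward elimination then removes effects whose removal increases the
#' objective by less than `backward` (default 6.63, p < 0.01). After each
#' forward step, remaining candidates whose univariate objective drop was
#' below `forward` *and* whose estimated effect lies inside the
#' irrelevance interval (default a +/-20\% parameter change) are dropped
#' from the scope. Candidate fits that fail are skipped and recorded.
#'
#' @param data event-record dataset.
#' @param model base `pk_model`.
#' @param candidates data frame with `param`, `cov`, `form`, `init`.
#' @param forward,backward likelihood-ratio thresholds on -2LL.
#' @param irrelevance half-width of the fractional irrelevance interval.
#' @param ... passed to [fit_population()].
#' @return list of class `scm_result`: `model` (final `pk_fit`),
#'   `selected` (data frame of retained effects), `trace` (decision log).
#' @export
scm_search <- function(data, model, candidates, forward = 3.84,
                       backward = 6.63, irrelevance = 0.20, ...) {
  stopifnot(all(c("param", "cov", "form", "init") %in% names(candidates)))
  if (is.null(model$covariates$fixed) && nrow(model$covariates))
    model$covariates$fixed <- TRUE
  trace <- list()
  note <- function(step, cand, dofv, decision)
    trace[[length(trace) + 1]] <<- data.frame(step = step, candidate = cand,
                                              delta_ofv = dofv, decision = decision)
  add_effect <- function(m, cand, fixed = FALSE) {
    m$covariates <- rbind(m$covariates,
      data.frame(param = cand$param, cov = cand$cov, form = cand$form,
                 value = cand$init, fixed = fixed))
    m
  }
  fit0 <- fit_population(data, model, hessian = FALSE, ...)
  current <- fit0; scope <- candidates
  step <- 0
  repeat {
    step <- step + 1
    if (!nrow(scope)) break
    res <- vector("list", nrow(scope))
    for (i in seq_len(nrow(scope))) {
      cand <- scope[i, ]
      f <- tryCatch(fit_population(data, add_effect(current, cand),
                                   hessian = FALSE, ...),
                    error = function(e) NULL)
      if (is.null(f)) {
        note(paste0("forward-", step), paste(cand$param, cand$cov, sep = "~"),
             NA_real_, "fit failed, skipped")
        next
      }
      res[[i]] <- list(cand = cand, fit = f, dofv = current$ofv - f$ofv,
        eff = f$covariates$value[nrow(f$covariates)])
    }
    ok <- !vapply(res, is.null, TRUE)
    if (!any(ok)) break
    dofvs <- vapply(res[ok], function(r) r$dofv, 0)
    best <- res[ok][[which.max(dofvs)]]
    lbl <- function(r) paste(r$cand$param, r$cand$cov, sep = "~")
    if (best$dofv > forward) {
      note(paste0("forward-", step), lbl(best), best$dofv, "included")
      current <- best$fit
      scope <- scope[!(scope$param == best$cand$param & scope$cov == best$cand$cov), ]
      ## adaptive scope reduction on the remaining candidates
      for (r in res[ok]) {
        if (identical(r$cand, best$cand)) next
        small <- if (r$cand$form == "frac") abs(r$eff) < irrelevance
                 else abs(2^r$eff - 1) < irrelevance
        if (r$dofv < forward && small) {
          note(paste0("forward-", step), lbl(r), r$dofv,
               "dropped from scope (irrelevant)")
          scope <- scope[!(scope$param == r$cand$param & scope$cov == r$cand$cov), ]
        }
      }
    } else {
      for (r in res[ok]) note(paste0("forward-", step), lbl(r), r$dofv,
                              "not included")
      break
    }
  }
  ## backward elimination
  repeat {
    free <- which(!current$covariates$fixed)
    if (!length(free)) break
    worst <- NULL
    for (i in free) {
      m <- current
      m$covariates <- m$covariates[-i, ]
      f <- tryCatch(fit_population(data, m, hessian = FALSE, ...),
                    error = function(e) NULL)
      if (is.null(f)) next
      dofv <- f$ofv - current$ofv  # increase when effect removed
      if (is.null(worst) || dofv < worst$dofv)
        worst <- list(i = i, fit = f, dofv = dofv)
    }
    if (is.null(worst)) break
    eff <- current$covariates[worst$i, ]
    if (worst$dofv < backward) {
      note("backward", paste(eff$param, eff$cov, sep = "~"), worst$dofv, "removed")
      current <- worst$fit
    } else {
      note("backward", paste(eff$param, eff$cov, sep = "~"), worst$dofv, "retained")
      break
    }
  }
  selected <- current$covariates[!current$covariates$fixed, , drop = FALSE]
  structure(list(model = current, selected = selected,
                 trace = do.call(rbind, trace)), class = "scm_result")
}

## ---- visual predictive check ----------------------------------------------

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the model on the original
#' design (same subjects, doses and sampling times), bins observations by
#' time and compares observed 5/50/95th percentiles with the simulated
#' distribution of those percentiles.
#'
#' @param model `pk_model` (typically a `pk_fit`).
#' @param data event-record dataset providing the design and observations.
#' @param n_sim number of replicates (>= 1; 100+ recommended).
#' @param seed integer seed (bands are deterministic under it).
#' @param breaks time bin boundaries (h); default octile-based.
#' @return data frame per bin: observed percentiles and the 5th/50th/95th
#'   percentile of each simulated percentile across replicates.
#' @export
vpc <- function(model, data, n_sim = 200, seed = 1, breaks = NULL) {
  obs <- data[data$EVID == 0 & data$MDV == 0, ]
  if (is.null(breaks))
    breaks <- unique(quantile(obs$TIME, seq(0, 1, length.out = 9)))
  bin <- function(t) cut(t, breaks, include.lowest = TRUE)
  set.seed(seed)
  enames <- names(model$omega)[model$omega > 0]
  subs <- .prep_subjects(data, "m1")
  qs <- c(0.05, 0.5, 0.95)
  sim_pct <- array(NA_real_, c(n_sim, length(levels(bin(obs$TIME))), 3))
  for (r in seq_len(n_sim)) {
    yy <- tt <- numeric(0)
    for (s in subs) {
      eta <- rnorm(length(enames), 0, sqrt(model$omega[enames]))
      f <- .pk_predict(s, eta, model, enames)
      y <- f * (1 + rnorm(length(f), 0, model$sigma["prop"])) +
        rnorm(length(f), 0, model$sigma["add"])
      yy <- c(yy, y); tt <- c(tt, s$t)
    }
    b <- bin(tt)
    for (j in seq_along(levels(b))) {
      if (!any(b == levels(b)[j], na.rm = TRUE)) next
      sim_pct[r, j, ] <- quantile(yy[which(b == levels(b)[j])], qs)
    }
  }
  ob <- bin(obs$TIME)
  out <- list()
  for (j in seq_along(levels(ob))) {
    sel <- which(ob == levels(ob)[j])
    if (!length(sel)) { warning("empty time bin dropped: ", levels(ob)[j]); next }
    op <- quantile(obs$DV[sel], qs)
    band <- apply(sim_pct[, j, , drop = FALSE], 3, quantile,
                  probs = c(0.05, 0.5, 0.95), na.rm = TRUE)
    out[[length(out) + 1]] <- data.frame(
      bin = levels(ob)[j], t_mid = mean(obs$TIME[sel]), n = length(sel),
      obs_p5 = op[1], obs_p50 = op[2], obs_p95 = op[3],
      sim_p5_lo = band[1, 1], sim_p5_med = band[2, 1], sim_p5_hi = band[3, 1],
      sim_p50_lo = band[1, 2], sim_p50_med = band[2, 2], sim_p50_hi = band[3, 2],
      sim_p95_lo = band[1, 3], sim_p95_med = band[2, 3], sim_p95_hi = band[3, 3])
  }
  do.call(rbind, out)
}
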