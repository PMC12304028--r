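## Nonlinear mixed-effects estimation: FOCE-with-interaction objective,
## empirical Bayes modes, maximum-likelihood fitting with a numerical
## Hessian, and helpers shared by the SCM search and the VPC.

## ---- low-level engine ------------------------------------------------------

#' FOCE-with-interaction objective for an arbitrary subject list
#'
#' The estimation core, independent of the PK plumbing. Each subject is a
#' list with at least `y` (observations); `predict_fn(subject, eta)` returns
#' the model prediction vector. The residual variance is
#' `v = (sigma_prop * f)^2 + sigma_add^2`, evaluated at the conditional
#' prediction (interaction). For each subject the conditional mode
#' `eta_hat` maximises the joint density of data and random effects; the
#' marginal -2 log-likelihood is approximated by linearising the model
#' about `eta_hat`:
#' \deqn{-2LL_i \approx n_i\log 2\pi + \log|V_i| + r_i' V_i^{-1} r_i,}
#' \eqn{V_i = G_i \Omega G_i' + diag(v_i)},
#' \eqn{r_i = y_i - f(\hat\eta_i) + G_i\hat\eta_i}. This is exact when the
#' model is linear in `eta` with constant variance.
#'
#' @param subjects list of subject lists (`y` plus whatever `predict_fn`
#'   needs).
#' @param predict_fn function(subject, eta) -> prediction vector.
#' @param omega diagonal of the between-subject covariance (length = eta
#'   dimension), all `> 0`.
#' @param sigma `c(prop, add)` residual parameters.
#' @param eta_init optional matrix (n_subjects x n_eta) of inner starting
#'   values (warm starts).
#' @param inner_tol inner optimiser tolerance.
#' @details Subjects may carry a logical `cens` vector and an `lloq`
#'   scalar: censored records then contribute the censored-normal
#'   likelihood `Phi((lloq - f)/sqrt(v))` (the M3 policy) and the
#'   subject's marginal likelihood is approximated by a Laplace
#'   approximation at the mode (exact for models linear in `eta`), since
#'   the linearised-covariance form does not apply to censored terms.
#' @return list `ofv` (scalar, includes the `n log 2pi` constant), `eta`
#'   (matrix of conditional modes), per-subject `ofv_i`.
#' @export
foce_engine <- function(subjects, predict_fn, omega, sigma,
                        eta_init = NULL, inner_tol = 1e-9) {
  neta <- length(omega)
  if (any(omega <= 0)) stop("engine requires strictly positive omega diagonal")
  sp <- sigma[1]; sa <- sigma[2]
  n <- length(subjects)
  etam <- matrix(0, n, neta)
  ofv_i <- numeric(n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    y <- s$y
    cens <- if (!is.null(s$cens)) s$cens else rep(FALSE, length(y))
    ## -2 log joint density of (data, eta), constants included
    q2 <- function(eta) {
      f <- predict_fn(s, eta)
      v <- pmax((sp * f)^2 + sa^2, 1e-12)
      ll_obs <- sum(log(2 * pi * v[!cens]) +
                      (y[!cens] - f[!cens])^2 / v[!cens])
      ll_cens <- if (any(cens))
        -2 * sum(pnorm((s$lloq - f[cens]) / sqrt(v[cens]), log.p = TRUE))
      else 0
      ll_obs + ll_cens + sum(eta^2 / omega) + sum(log(2 * pi * omega))
    }
    q <- function(eta) q2(eta)   # same maximiser, used by both branches
    start <- if (!is.null(eta_init)) eta_init[i, ] else rep(0, neta)
    opt <- nlminb(start, q, control = list(rel.tol = inner_tol))
    if (opt$convergence != 0 && opt$convergence != 1)
      stop("inner non-convergence for subject ", i, ": ", opt$message)
    eta_hat <- opt$par
    etam[i, ] <- eta_hat
    if (any(cens)) {
      ## Laplace: -2LL = q2(mode) - d log(2pi) + log det(q2''(mode)/2)
      h <- 1e-4
      H <- matrix(0, neta, neta)
      q0 <- q2(eta_hat)
      for (a in seq_len(neta)) for (b in a:neta) {
        if (a == b) {
          ep <- em <- eta_hat; ep[a] <- ep[a] + h; em[a] <- em[a] - h
          H[a, a] <- (q2(ep) - 2 * q0 + q2(em)) / h^2
        } else {
          epp <- epm <- emp <- emm <- eta_hat
          epp[c(a, b)] <- epp[c(a, b)] + h
          epm[a] <- epm[a] + h; epm[b] <- epm[b] - h
          emp[a] <- emp[a] - h; emp[b] <- emp[b] + h
          emm[c(a, b)] <- emm[c(a, b)] - h
          H[a, b] <- H[b, a] <- (q2(epp) - q2(epm) - q2(emp) + q2(emm)) /
            (4 * h^2)
        }
      }
      ofv_i[i] <- q0 - neta * log(2 * pi) +
        as.numeric(determinant(H / 2)$modulus)
      next
    }
    f_hat <- predict_fn(s, eta_hat)
    v_hat <- pmax((sp * f_hat)^2 + sa^2, 1e-12)
    ## linearisation G = df/deta at the mode (central differences)
    G <- matrix(0, length(y), neta)
    h <- 1e-4
    for (k in seq_len(neta)) {
      ep <- eta_hat; ep[k] <- ep[k] + h
      em <- eta_hat; em[k] <- em[k] - h
      G[, k] <- (predict_fn(s, ep) - predict_fn(s, em)) / (2 * h)
    }
    V <- G %*% (diag(omega, neta)) %*% t(G) + diag(v_hat, length(y))
    r <- y - f_hat + as.numeric(G %*% eta_hat)
    ch <- tryCatch(chol(V), error = function(e)
      stop("objective error: singular linearised covariance for subject ", i))
    ofv_i[i] <- length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
      sum(backsolve(ch, r, transpose = TRUE)^2)
  }
  list(ofv = sum(ofv_i), eta = etam, ofv_i = ofv_i)
}

## ---- PK dataset plumbing ---------------------------------------------------

## split an event-record dataset into fitting subjects
.prep_subjects <- function(data, blq = c("m1", "m3"), lloq = 0.01) {
  blq <- match.arg(blq)
  subs <- list()
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, ]
    doses <- d[d$EVID == 1, c("TIME", "AMT", "DUR", "ROUTE", "DOSENO")]
    names(doses) <- c("time", "amt", "dur", "route", "dose_ordinal")
    obs <- d[d$EVID == 0, ]
    if (blq == "m1") obs <- obs[obs$BLQ == 0 & !is.na(obs$DV), ]
    if (!nrow(obs) || !nrow(doses)) next
    subs[[length(subs) + 1]] <-
      list(id = id, t = obs$TIME, y = ifelse(is.na(obs$DV), lloq, obs$DV),
           cens = obs$BLQ == 1, doses = doses, cov = d[1, ], lloq = lloq)
  }
  subs
}

## individual prediction at given theta-model and eta
.pk_predict <- function(sub, eta, model, enames, rtol = 1e-6) {
  p <- apply_covariates(model, sub$cov)
  p[enames] <- p[enames] * exp(eta)
  if (p["Vmax"] == 0 && all(sub$doses$route == "IV"))
    .lin_conc(p["CL"], p["Vc"], sub$doses, sub$t)
  else solve_activity(p, sub$doses, sub$t, rtol = rtol, atol = rtol * 1e-2)
}

#' Empirical Bayes estimates (conditional modes) of the random effects
#'
#' @param data event-record dataset.
#' @param model `pk_model` with at least one positive omega entry.
#' @param blq BLQ policy (`"m1"` discards BLQ records).
#' @return matrix of per-subject conditional modes (columns = parameters
#'   with between-subject variability), rownames = subject IDs.
#' @export
conditional_modes <- function(data, model, blq = "m1") {
  enames <- names(model$omega)[model$omega > 0]
  if (!length(enames)) stop("model has no random effects")
  subs <- .prep_subjects(data, blq)
  eng <- foce_engine(subs, function(s, eta) .pk_predict(s, eta, model, enames),
                     omega = model$omega[enames], sigma = model$sigma)
  m <- eng$eta
  dimnames(m) <- list(vapply(subs, function(s) as.character(s$id), ""), enames)
  m
}

#' FOCEI objective (-2 log-likelihood approximation) of a dataset
#'
#' Dispatches to a fully vectorised evaluation when the model is linear
#' (Vmax = 0), the dosing history is IV-only and the single random effect
#' is on `CL`; otherwise uses the generic engine (ODE-backed predictions).
#'
#' @inheritParams conditional_modes
#' @param warm environment used internally to carry inner warm starts
#'   between calls (optional).
#' @return scalar objective (includes additive `n log 2pi` constants).
#' @export
foce_ofv <- function(data, model, blq = "m1", warm = NULL) {
  subs <- .prep_subjects(data, blq)
  .foce_ofv_subs(subs, model, warm)
}

.foce_ofv_subs <- function(subs, model, warm = NULL) {
  enames <- names(model$omega)[model$omega > 0]
  if (!length(enames)) stop("model has no random effects")
  fast <- identical(enames, "CL") && model$theta["Vmax"] == 0 &&
    all(vapply(subs, function(s) all(s$doses$route == "IV") && !any(s$cens), TRUE))
  if (fast) return(.foce_fast(subs, model, warm))
  init <- if (!is.null(warm) && !is.null(warm$eta)) warm$eta else NULL
  eng <- foce_engine(subs, function(s, eta) .pk_predict(s, eta, model, enames),
                     omega = model$omega[enames], sigma = model$sigma,
                     eta_init = init)
  if (!is.null(warm)) warm$eta <- eng$eta
  eng$ofv
}

## vectorised typical values for one parameter across subjects
.typ_vec <- function(model, cov_cols, param, n) {
  out <- rep(unname(model$theta[param]), n)
  ce <- model$covariates
  for (i in which(ce$param == param)) {
    x <- cov_cols[[ce$cov[i]]]
    if (is.null(x)) stop("subjects lack covariate ", ce$cov[i])
    if (ce$form[i] == "power") {
      ref <- if (ce$cov[i] == "BSA") REF_BSA else 1
      out <- out * (as.numeric(x) / ref)^ce$value[i]
    } else out <- out * (1 + ce$value[i] * as.numeric(x))
  }
  out
}

## vectorised FOCEI for the linear-IV / eta-on-CL case
.foce_fast <- function(subs, model, warm = NULL) {
  key <- "fastcache"
  cache <- if (!is.null(warm) && !is.null(warm[[key]])) warm[[key]] else {
    ## expanded design: one row per (observation, dose) pair
    n <- length(subs)
    si <- integer(0); tt <- numeric(0); yy <- numeric(0); rowid <- integer(0)
    amt <- numeric(0); dur <- numeric(0); tdiff <- numeric(0); xrow <- integer(0)
    nr <- 0L
    covs <- do.call(rbind, lapply(subs, function(s) s$cov))
    for (i in seq_len(n)) {
      s <- subs[[i]]
      m <- length(s$t)
      idx <- nr + seq_len(m)
      si <- c(si, rep(i, m)); tt <- c(tt, s$t); yy <- c(yy, s$y)
      for (d in seq_len(nrow(s$doses))) {
        xrow <- c(xrow, idx)
        amt <- c(amt, rep(s$doses$amt[d], m))
        dur <- c(dur, rep(s$doses$dur[d], m))
        tdiff <- c(tdiff, s$t - s$doses$time[d])
      }
      nr <- nr + m
    }
    cov_cols <- lapply(covs, function(x) if (is.factor(x)) as.character(x) else x)
    list(n = n, si = si, yy = yy, nrow = nr, xrow = xrow, amt = amt,
         dur = dur, tdiff = tdiff, cov_cols = cov_cols,
         nobs = as.numeric(table(factor(si, levels = seq_len(n)))))
  }
  if (!is.null(warm)) warm[[key]] <- cache

  CLi <- .typ_vec(model, cache$cov_cols, "CL", cache$n)
  Vci <- .typ_vec(model, cache$cov_cols, "Vc", cache$n)
  sp <- model$sigma["prop"]; sa <- model$sigma["add"]
  om <- unname(model$omega["CL"])
  xs <- cache$si[cache$xrow]

  Fv <- function(eta) {            # prediction for every observation row
    CL <- CLi[xs] * exp(eta[xs]); Vc <- Vci[xs]
    k <- CL / Vc
    R0 <- cache$amt / cache$dur
    td <- cache$tdiff
    A <- ifelse(td <= 0, 0,
          ifelse(td <= cache$dur,
                 R0 / k * (1 - exp(-k * td)),
                 R0 / k * (1 - exp(-k * cache$dur)) * exp(-k * (td - cache$dur))))
    as.numeric(rowsum(A / (Vc * 1000), cache$xrow, reorder = TRUE))
  }
  grp <- function(x) as.numeric(rowsum(x, cache$si, reorder = TRUE))
  Q <- function(eta) {             # per-subject inner objective vector
    f <- Fv(eta)
    v <- pmax((sp * f)^2 + sa^2, 1e-12)
    grp(log(v) + (cache$yy - f)^2 / v) + eta^2 / om
  }
  eta <- if (!is.null(warm) && !is.null(warm$eta_fast)) warm$eta_fast
         else rep(0, cache$n)
  h <- 1e-3
  for (it in 1:30) {               # vectorised damped Newton on the modes
    q0 <- Q(eta); qp <- Q(eta + h); qm <- Q(eta - h)
    d1 <- (qp - qm) / (2 * h)
    d2 <- pmax((qp - 2 * q0 + qm) / h^2, 1e-4)
    step <- pmax(pmin(-d1 / d2, 0.5), -0.5)
    eta <- eta + step
    if (max(abs(step)) < 1e-8) break
  }
  if (!is.null(warm)) warm$eta_fast <- eta
  f_hat <- Fv(eta)
  g <- (Fv(eta + h) - Fv(eta - h)) / (2 * h)
  v <- pmax((sp * f_hat)^2 + sa^2, 1e-12)
  r <- cache$yy - f_hat + g * eta[cache$si]
  a <- grp(g^2 / v); b <- grp(g * r / v); cc <- grp(r^2 / v); s <- grp(log(v))
  sum(cache$nobs * log(2 * pi) + s + log1p(om * a) +
        cc - om * b^2 / (1 + om * a))
}
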