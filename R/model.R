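#' @importFrom stats qbeta quantile rnorm rbinom runif setNames lm coef median sd optimize nlminb qnorm pnorm dnorm approx aggregate
#' @importFrom utils head tail read.csv write.csv type.convert
NULL

#' Reference body surface area (m^2) for covariate scaling
#'
#' Continuous covariate effects are parameterised relative to a reference
#' patient with a BSA of 0.835 m^2 (non-Japanese, ADA-negative).
#' @export
REF_BSA <- 0.835

## ---- model object ----------------------------------------------------------

#' Construct a population PK model specification
#'
#' The structural model is a one-compartment model with IV-infusion or
#' first-order IM input and parallel linear + Michaelis-Menten elimination:
#' \deqn{dA/dt = input(t) + ka A_d - (CL/Vc) A - Vmax C/(Km + C), \quad
#'       C = A/(1000 Vc)}
#' where `A` is the amount (IU) in the central compartment, `C` the plasma
#' asparaginase activity (IU/ml), `CL` the linear clearance (L/h), `Vc` the
#' central volume (L), `Vmax` (IU/h) and `Km` (IU/ml) the saturable pathway,
#' and `A_d` the IM depot. IM doses enter the depot scaled by a
#' first-dose/later-dose bioavailability.
#'
#' @param theta named numeric vector of typical values: `CL` (L/h), `Vc` (L),
#'   `Vmax` (IU/h), `Km` (IU/ml), and for IM input `ka` (1/h), `F_first`,
#'   `F_later` (fractions in (0, 1]).
#' @param covariates data frame with columns `param`, `cov`, `form`
#'   (`"power"` for continuous covariates, exponent in `value`, reference
#'   `REF_BSA` for BSA; `"frac"` for 0/1 indicators, fractional shift in
#'   `value`, must be > -1) and `value`. May have zero rows.
#' @param omega named numeric vector of log-scale between-subject variances
#'   (diagonal Omega); names must be a subset of structural parameter names.
#' @param sigma named numeric vector `c(prop = , add = )`: proportional CV and
#'   additive SD (IU/ml) of the residual error `y = f (1 + eps_p) + eps_a`.
#' @return an object of class `pk_model`.
#' @export
pk_model <- function(theta, covariates = NULL, omega = NULL,
                     sigma = c(prop = 0.1, add = 0.005)) {
  theta <- unlist(theta)
  if (any(theta[intersect(names(theta), c("CL", "Vc", "Vmax", "Km", "ka"))] < 0))
    stop("structural typical values must be non-negative")
  for (f in intersect(c("F_first", "F_later"), names(theta)))
    if (theta[f] <= 0 || theta[f] > 1) stop(f, " must be in (0, 1]")
  if (is.null(covariates))
    covariates <- data.frame(param = character(), cov = character(),
                             form = character(), value = numeric())
  stopifnot(all(c("param", "cov", "form", "value") %in% names(covariates)))
  if (any(covariates$form == "frac" & covariates$value <= -1))
    stop("fractional covariate shifts must be > -1")
  if (is.null(omega)) omega <- c(CL = 0, Vc = 0, Vmax = 0)
  if (any(omega < 0)) stop("omega variances must be >= 0")
  sigma <- c(prop = unname(sigma["prop"]), add = unname(sigma["add"]))
  if (any(is.na(sigma)) || any(sigma < 0)) stop("sigma must be named (prop, add), >= 0")
  structure(list(theta = theta, covariates = covariates, omega = omega,
                 sigma = sigma, vcov = NULL, ofv = NA_real_),
            class = "pk_model")
}

#' Default population model of the synthetic trial generator
#'
#' Typical values are package defaults calibrated so a noise-free reference
#' subject reproduces the magnitudes of the trial's dose-group PK summaries
#' (Cmax about 1.4 IU/ml, terminal half-life on the order of 120 h). They are
#' not estimates from any patient dataset. BSA acts as a power covariate
#' (exponent 1) on `CL`, `Vc` and `Vmax`; no categorical effect is active by
#' default (the emulated trial population is homogeneous).
#'
#' @param bsv logical; include the default diagonal between-subject
#'   variability (30\% CV on `CL`, `Vc`, `Vmax`)?
#' @return a `pk_model`.
#' @export
default_model <- function(bsv = TRUE) {
  theta <- c(CL = 0.0067, Vc = 1.5, Vmax = 5.74, Km = 2,
             ka = 0.05, F_first = 0.8, F_later = 0.7)
  covs <- data.frame(param = c("CL", "Vc", "Vmax"),
                     cov = "BSA", form = "power", value = 1)
  om <- if (bsv) c(CL = 0.09, Vc = 0.09, Vmax = 0.09) else c(CL = 0, Vc = 0, Vmax = 0)
  pk_model(theta, covs, om, sigma = c(prop = 0.10, add = 0.005))
}

## ---- covariate mapping -----------------------------------------------------

#' Map typical values and subject covariates to individual parameters
#'
#' For each structural parameter P:
#' \deqn{P_i = \theta_P (BSA_i/0.835)^{e_P} \prod_k (1 + \beta_k x_{ik})}
#' with power effects for continuous covariates and fractional shifts
#' (`beta`) for 0/1 indicators. No random effects are applied here.
#'
#' @param model a `pk_model`, or a named theta vector (then `covariates` must
#'   be supplied via `model$covariates` of a `pk_model`).
#' @param subject a one-row data frame or list with the covariates referenced
#'   by the model (`BSA` in m^2; indicators such as `POP` = 1 for Japanese,
#'   `SEX`, `ADA` as 0/1).
#' @return named numeric vector of individual structural parameters.
#' @export
apply_covariates <- function(model, subject) {
  stopifnot(inherits(model, "pk_model"))
  p <- model$theta
  ce <- model$covariates
  if (nrow(ce)) {
    for (i in seq_len(nrow(ce))) {
      par <- ce$param[i]; cv <- ce$cov[i]
      x <- subject[[cv]]
      if (is.null(x) || is.na(x)) stop("subject lacks covariate ", cv)
      if (ce$form[i] == "power") {
        if (x <= 0) stop("invalid covariate: non-positive ", cv)
        ref <- if (cv == "BSA") REF_BSA else 1
        p[par] <- p[par] * (x / ref)^ce$value[i]
      } else if (ce$form[i] == "frac") {
        p[par] <- p[par] * (1 + ce$value[i] * as.numeric(x))
      } else stop("unknown covariate form ", ce$form[i])
    }
  }
  bad <- names(p)[p <= 0 & names(p) %in% c("CL", "Vc", "Km")]
  if (length(bad)) stop("invalid coefficients: non-positive ", paste(bad, collapse = ", "))
  p
}

## ---- closed forms ----------------------------------------------------------

#' Closed-form one-compartment activity for a zero-order IV infusion
#'
#' Exact solution with linear elimination only, used throughout as an
#' analytic reference for the numerical solver and as the fast evaluation
#' path for linear-model fits.
#'
#' @param CL clearance (L/h); @param Vc central volume (L)
#' @param dose amount (IU); @param infusion_duration length of infusion (h)
#' @param t vector of times (h) since infusion start
#' @return activity (IU/ml) at `t` (0 before the infusion starts).
#' @export
closed_form_linear_iv <- function(CL, Vc, dose, infusion_duration, t) {
  stopifnot(CL > 0, Vc > 0, dose > 0, infusion_duration > 0)
  k <- CL / Vc
  R0 <- dose / infusion_duration
  A <- ifelse(t <= 0, 0,
         ifelse(t <= infusion_duration,
                R0 / k * (1 - exp(-k * t)),
                R0 / k * (1 - exp(-k * infusion_duration)) *
                  exp(-k * (t - infusion_duration))))
  A / (Vc * 1000)
}

## superposition of a dose table under linear kinetics (internal fast path)
.lin_conc <- function(CL, Vc, doses, t) {
  out <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    if (doses$route[d] != "IV") stop("linear closed form supports IV doses only")
    out <- out + closed_form_linear_iv(CL, Vc, doses$amt[d], doses$dur[d],
                                       t - doses$time[d])
  }
  out
}

## ---- ODE solution ----------------------------------------------------------

.pk_deriv <- function(t, y, p) {
  C <- y[1] / (p$Vc * 1000)
  dA <- p$rate + p$ka * y[2] - (p$CL / p$Vc) * y[1] - p$Vmax * C / (p$Km + C)
  list(c(dA, -p$ka * y[2]))
}

#' Solve the structural model for an arbitrary dosing history
#'
#' Integrates the one-compartment model with parallel linear and saturable
#' elimination piecewise between dose events, so infusion start/stop
#' discontinuities fall on exact breakpoints and are never smoothed over.
#' IM doses are placed in a depot scaled by `F_first` (first IM dose) or
#' `F_later`; IV doses enter as a zero-order rate over the infusion window.
#'
#' @param params named vector of individual structural parameters (see
#'   [apply_covariates()]); `Vmax = 0` gives the purely linear model.
#' @param doses data frame with columns `time` (h), `amt` (IU), `route`
#'   (`"IV"`/`"IM"`), `dur` (h, IV infusion duration), `dose_ordinal`
#'   (1-based IM dose index used for bioavailability selection).
#' @param times non-decreasing numeric vector of output times (h).
#' @param rtol,atol solver tolerances (stiff-capable `deSolve::lsoda`).
#' @param method `"auto"` (default) uses the exact closed form when the
#'   model is linear (`Vmax = 0`) and the history is IV-only, otherwise
#'   the ODE integrator; `"ode"` forces numerical integration.
#' @return numeric vector of activities (IU/ml) at `times`, all `>= 0`.
#' @export
solve_activity <- function(params, doses, times, rtol = 1e-8, atol = 1e-10,
                           method = c("auto", "ode")) {
  method <- match.arg(method)
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (!nrow(doses)) stop("at least one dose required")
  if (any(doses$amt <= 0)) stop("dose amounts must be positive")
  iv <- doses$route == "IV"
  if (any(iv & !(doses$dur > 0))) stop("IV doses need a positive infusion duration")
  p <- as.list(params[c("CL", "Vc", "Vmax", "Km")])
  p$ka <- if ("ka" %in% names(params)) unname(params["ka"]) else 0
  t0 <- min(doses$time)
  out <- numeric(length(times))
  act <- times >= t0
  if (!any(act)) return(out)

  ## purely linear IV history: use the exact solution
  if (method == "auto" && p$Vmax == 0 && all(iv)) {
    out[act] <- .lin_conc(p$CL, p$Vc, doses, times[act])
    return(pmax(out, 0))
  }

  tmax <- max(times)
  bks <- sort(unique(c(doses$time, doses$time[iv] + doses$dur[iv])))
  bks <- c(bks[bks < tmax], tmax)
  y <- c(0, 0)
  res_t <- t0; res_c <- 0
  lo <- t0
  for (b in bks[bks > t0]) {
    ## depot boluses at segment start
    im_here <- which(!iv & abs(doses$time - lo) < 1e-12)
    for (d in im_here) {
      f <- if (doses$dose_ordinal[d] <= 1) params["F_first"] else params["F_later"]
      y[2] <- y[2] + unname(f) * doses$amt[d]
    }
    p$rate <- sum(doses$amt[iv] / doses$dur[iv] *
                    (doses$time[iv] <= lo + 1e-12 & doses$time[iv] + doses$dur[iv] >= b - 1e-12))
    seg_t <- sort(unique(c(lo, times[times > lo & times <= b], b)))
    sol <- tryCatch(
      deSolve::lsoda(y, seg_t, .pk_deriv, p, rtol = rtol, atol = atol),
      warning = function(w) stop("numerical integration failed near t = ", lo,
                                 ": ", conditionMessage(w)))
    y <- as.numeric(sol[nrow(sol), 2:3])
    res_t <- c(res_t, seg_t[-1]); res_c <- c(res_c, sol[-1, 2] / (p$Vc * 1000))
    lo <- b
  }
  out[act] <- approx(res_t, res_c, xout = times[act], ties = "ordered")$y
  pmax(out, 0)
}
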