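# Independent numerical oracles used to cross-check the implementation.
# Each is written from first principles and shares no code with R/.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix)
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# adaptive 64-node GH marginal -2LL for a 1-dim random effect
agq_m2ll <- function(subjects, pred, omega, sigma, nodes = 64) {
  g <- gh_rule(nodes)
  sp <- sigma[1]; sa <- sigma[2]
  sum(vapply(subjects, function(s) {
    lj <- function(eta) {
      f <- pred(s, eta)
      v <- (sp * f)^2 + sa^2
      sum(dnorm(s$y, f, sqrt(v), log = TRUE)) +
        dnorm(eta, 0, sqrt(omega), log = TRUE)
    }
    mode <- optimize(function(e) -lj(e), c(-4, 4))$minimum
    h <- 1e-4
    curv <- -(lj(mode + h) - 2 * lj(mode) + lj(mode - h)) / h^2
    s2 <- 1 / curv
    x <- mode + sqrt(2 * s2) * g$x
    lw <- log(g$w) + g$x^2 + vapply(x, lj, 0) + 0.5 * log(2 * s2)
    M <- max(lw)
    -2 * (M + log(sum(exp(lw - M))))
  }, 0))
}

# fixed-step classical RK4 for the one-compartment MM+linear model,
# single IV infusion starting at t = 0
rk4_mm_iv <- function(CL, Vc, Vmax, Km, dose, dur, t_out, h) {
  # integrate each smooth phase separately so the infusion-stop
  # discontinuity never falls inside an RK4 step
  deriv <- function(A, rate) {
    C <- A / (Vc * 1000)
    rate - (CL / Vc) * A - Vmax * C / (Km + C)
  }
  run <- function(a0, t0, t1, rate) {
    ts <- seq(t0, t1, by = h)
    if (ts[length(ts)] < t1) ts <- c(ts, t1)
    A <- numeric(length(ts)); A[1] <- a0
    for (i in seq_len(length(ts) - 1)) {
      hh <- ts[i + 1] - ts[i]
      k1 <- deriv(A[i], rate)
      k2 <- deriv(A[i] + hh / 2 * k1, rate)
      k3 <- deriv(A[i] + hh / 2 * k2, rate)
      k4 <- deriv(A[i] + hh * k3, rate)
      A[i + 1] <- A[i] + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    list(t = ts, A = A)
  }
  p1 <- run(0, 0, dur, dose / dur)
  p2 <- run(p1$A[length(p1$A)], dur, max(c(t_out, dur + h)), 0)
  tt <- c(p1$t, p2$t[-1]); AA <- c(p1$A, p2$A[-1])
  approx(tt, AA / (Vc * 1000), xout = t_out)$y
}

# brute-force terminal-slope search: every window of >= 3 points ending at
# the last positive observation, slope via closed-form least squares
brute_lambda_z <- function(times, conc) {
  keep <- conc > 0
  times <- times[keep]; conc <- conc[keep]
  imax <- which.max(conc)[1]
  tt <- times[-seq_len(imax)]; yy <- log(conc[-seq_len(imax)])
  best <- NULL
  for (start in seq_len(length(tt) - 2)) {
    x <- tt[start:length(tt)]; y <- yy[start:length(tt)]
    n <- length(x)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    if (!is.finite(sl) || sl >= 0) next
    res <- y - mean(y) - sl * (x - mean(x))
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    ar2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || ar2 > best$ar2 + 1e-12)
      best <- list(lambda = -sl, ar2 = ar2, n = n)
  }
  best
}

# single-IV-dose helpers
one_dose <- function(amt, dur = 2, time = 0)
  data.frame(time = time, amt = amt, route = "IV", dur = dur, dose_ordinal = 1)

ref_subject <- function(...) {
  s <- data.frame(BSA = 0.835, WT = 20, SEX = 0, POP = 0, ADA = 0, RISK = "SR")
  dots <- list(...)
  for (nm in names(dots)) s[[nm]] <- dots[[nm]]
  s
}

# linear-model pk_model used in estimation tests (eta on CL only)
lin_model <- function(beta_pop_cl = NULL, omega_cl = 0.09,
                      sigma = c(prop = 0.1, add = 0.002)) {
  cov <- data.frame(param = c("CL", "Vc"), cov = "BSA", form = "power",
                    value = 1, fixed = TRUE)
  if (!is.null(beta_pop_cl))
    cov <- rbind(cov, data.frame(param = "CL", cov = "POP", form = "frac",
                                 value = beta_pop_cl, fixed = TRUE))
  pk_model(c(CL = 0.0067, Vc = 1.5, Vmax = 0, Km = 2),
           covariates = cov, omega = c(CL = omega_cl, Vc = 0, Vmax = 0),
           sigma = sigma)
}
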