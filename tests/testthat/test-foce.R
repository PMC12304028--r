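# Estimation tests: the FOCEI objective against analytic and quadrature
# oracles, conditional modes, and small-scale fitting behaviour.

test_that("FOCEI equals the exact marginal -2LL for a linear-in-eta model", {
  set.seed(1)
  m <- 5
  subjects <- lapply(1:8, function(i) {
    x <- seq(0, 2, length.out = m)
    list(x = x, y = 1 + 0.5 * rnorm(1) * x + rnorm(m, 0, 0.3))
  })
  om <- 0.25; sa <- 0.3
  eng <- foce_engine(subjects, function(s, eta) 1 + eta * s$x,
                     omega = om, sigma = c(0, sa))
  exact <- sum(vapply(subjects, function(s) {
    V <- sa^2 * diag(m) + om * outer(s$x, s$x)
    r <- s$y - 1
    as.numeric(m * log(2 * pi) + determinant(V)$modulus + t(r) %*% solve(V, r))
  }, 0))
  expect_equal(eng$ofv, exact, tolerance = 1e-10)
})

test_that("FOCEI is within 1% of 64-node adaptive Gauss-Hermite on a nonlinear toy", {
  set.seed(2)
  k <- 0.01; th <- 1.4; om <- 0.09
  span <- c(0, 24, 96, 240, 400)
  subjects <- lapply(1:6, function(i) {
    eta <- rnorm(1, 0, sqrt(om))
    f <- th * exp(eta) * exp(-k * span)
    list(t = span, y = f * (1 + rnorm(5, 0, 0.1)))
  })
  pred <- function(s, eta) th * exp(eta) * exp(-k * s$t)
  sig <- c(0.1, 0.001)
  eng <- foce_engine(subjects, pred, omega = om, sigma = sig)
  orc <- agq_m2ll(subjects, pred, om, sig)
  expect_lt(abs(eng$ofv - orc) / abs(orc), 0.01)
})

test_that("rescaling data and additive error shifts the objective by the Jacobian", {
  set.seed(3)
  subjects <- lapply(1:5, function(i)
    list(t = c(1, 10, 50), y = exp(rnorm(1, 0, 0.3)) * exp(-0.02 * c(1, 10, 50)) +
           rnorm(3, 0, 0.05)))
  pred <- function(s, eta) exp(eta) * exp(-0.02 * s$t)
  o1 <- foce_engine(subjects, pred, omega = 0.09, sigma = c(0, 0.05))$ofv
  cst <- 10
  sub2 <- lapply(subjects, function(s) list(t = s$t, y = cst * s$y))
  pred2 <- function(s, eta) cst * exp(eta) * exp(-0.02 * s$t)
  o2 <- foce_engine(sub2, pred2, omega = 0.09, sigma = c(0, cst * 0.05))$ofv
  N <- 15
  expect_equal(o2, o1 + 2 * N * log(cst), tolerance = 1e-6)
})

test_that("conditional modes shrink to zero as Omega shrinks", {
  m <- lin_model(omega_cl = 1e-8)
  d <- simulate_cohort(cohort_spec(n_subjects = 5, model = lin_model(), seed = 4,
                                   phases = "induction"))
  eta <- conditional_modes(d, m)
  expect_lt(max(abs(eta)), 1e-3)
})

test_that("conditional mode matches a grid search for a single subject", {
  m <- lin_model()
  d <- simulate_cohort(cohort_spec(n_subjects = 1, model = m, seed = 6,
                                   phases = "induction"))
  eta_hat <- conditional_modes(d, m)[1, 1]
  # independent coarse-to-fine grid over the subject's joint density
  subs <- pegaspk:::.prep_subjects(d, "m1")
  s <- subs[[1]]
  q <- function(eta) {
    pars <- apply_covariates(m, s$cov)
    pars["CL"] <- pars["CL"] * exp(eta)
    f <- closed_form_linear_iv(pars["CL"], pars["Vc"], s$doses$amt[1],
                               s$doses$dur[1], s$t)
    v <- (m$sigma["prop"] * f)^2 + m$sigma["add"]^2
    sum(log(v) + (s$y - f)^2 / v) + eta^2 / m$omega["CL"]
  }
  grid <- seq(-2, 2, by = 1e-3)
  expect_lt(abs(eta_hat - grid[which.min(vapply(grid, q, 0))]), 2e-3)
})

test_that("conditional modes recover the generating eta as noise vanishes", {
  m <- lin_model(omega_cl = 0.09, sigma = c(prop = 1e-6, add = 1e-9))
  truth <- lin_model(omega_cl = 1e-12, sigma = c(prop = 0, add = 0))
  truth$theta["CL"] <- truth$theta["CL"] * exp(0.2)  # subject at eta = 0.2
  d <- simulate_cohort(cohort_spec(n_subjects = 3, model = truth, seed = 7,
                                   phases = "induction"))
  eta <- conditional_modes(d, m)
  expect_equal(unname(eta[, 1]), rep(0.2, 3), tolerance = 1e-3)
})

test_that("vectorised linear-path objective agrees with the generic engine", {
  m <- lin_model()
  d <- simulate_cohort(cohort_spec(n_subjects = 12, model = m, seed = 8,
                                   phases = "induction"))
  fast <- foce_ofv(d, m)
  subs <- pegaspk:::.prep_subjects(d, "m1")
  generic <- foce_engine(subs,
    function(s, eta) pegaspk:::.pk_predict(s, eta, m, "CL"),
    omega = m$omega["CL"], sigma = m$sigma)$ofv
  expect_equal(fast, generic, tolerance = 1e-6)
})

test_that("a noise-free dataset is refit to the generating fixed effects", {
  gen <- lin_model(omega_cl = 1e-12, sigma = c(prop = 0, add = 0))
  d <- simulate_cohort(cohort_spec(n_subjects = 12, model = gen, seed = 9,
                                   phases = "induction"))
  # residual SD fixed small: with proportional error the log-variance term
  # biases the optimum by O(sigma^2), so a noise-free refit is only exact
  # in the sigma -> 0 limit
  init <- lin_model(omega_cl = 0.04, sigma = c(prop = 1e-3, add = 1e-5))
  init$theta["CL"] <- 0.004; init$theta["Vc"] <- 2
  fit <- fit_population(d, init, est_theta = c("CL", "Vc"),
                        est_omega = character(0), est_sigma = character(0),
                        hessian = FALSE)
  expect_equal(unname(fit$theta["CL"]), 0.0067, tolerance = 1e-3)
  expect_equal(unname(fit$theta["Vc"]), 1.5, tolerance = 1e-3)
})

test_that("the optimum is stable across distinct starting values", {
  m <- lin_model()
  d <- simulate_cohort(cohort_spec(n_subjects = 30, model = m, seed = 10,
                                   phases = "induction"))
  ofvs <- vapply(list(c(0.004, 1.0, 0.2), c(0.01, 2.5, 0.4), c(0.0067, 1.5, 0.3)),
    function(st) {
      init <- lin_model(omega_cl = st[3]^2)
      init$theta["CL"] <- st[1]; init$theta["Vc"] <- st[2]
      fit_population(d, init, hessian = FALSE)$ofv
    }, 0)
  expect_lt(max(ofvs) - min(ofvs), 0.1)
})

test_that("fitted omega is non-negative by construction and vcov is symmetric PSD", {
  m <- lin_model()
  d <- simulate_cohort(cohort_spec(n_subjects = 25, model = m, seed = 11,
                                   phases = "induction"))
  fit <- fit_population(d, m, hessian = TRUE)
  expect_true(all(fit$omega >= 0))
  expect_false(is.null(fit$vcov))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("M3 censored-likelihood handling matches M1 without censoring and runs with it", {
  m <- lin_model()
  d <- simulate_cohort(cohort_spec(n_subjects = 8, model = m, seed = 12,
                                   phases = "induction", lloq = 0))
  # no BLQ records: both policies see the same data
  expect_equal(foce_ofv(d, m, blq = "m1"), foce_ofv(d, m, blq = "m3"),
               tolerance = 1e-6)
  # heavy censoring: M3 keeps the BLQ information and still evaluates
  d2 <- simulate_cohort(cohort_spec(n_subjects = 8, model = m, seed = 12,
                                    phases = "induction", lloq = 0.2))
  o1 <- foce_ofv(d2, m, blq = "m1")
  o3 <- foce_ofv(d2, m, blq = "m3")
  expect_true(is.finite(o3))
  expect_false(isTRUE(all.equal(o1, o3)))
})
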