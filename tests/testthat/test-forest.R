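# Forest-plot machinery: uncertainty sampling, exposure metrics, ratio
# identities against the 80-125% margins.

fit_small <- function() {
  d <- simulate_cohort(cohort_spec(n_subjects = 30, model = lin_model(), seed = 41,
                                   phases = "induction"))
  fit_population(d, lin_model(), hessian = TRUE)
}

test_that("uncertainty draws are deterministic and collapse when vcov = 0", {
  fit <- fit_small()
  d1 <- sample_parameter_sets(fit, n = 50, seed = 9)
  d2 <- sample_parameter_sets(fit, n = 50, seed = 9)
  expect_equal(d1[[17]]$theta, d2[[17]]$theta)
  fit0 <- fit
  fit0$vcov[] <- 0
  dz <- sample_parameter_sets(fit0, n = 10, seed = 1)
  for (m in dz) expect_equal(m$theta["CL"], fit$theta["CL"])
})

test_that("empirical covariance of many draws matches the fit's vcov", {
  fit <- fit_small()
  draws <- sample_parameter_sets(fit, n = 50000, seed = 3)
  x <- t(vapply(draws, function(m)
    c(log(m$theta[["CL"]]), log(m$theta[["Vc"]])), c(0, 0)))
  emp <- cov(x)
  expect_equal(emp[1, 1], fit$vcov["theta_CL", "theta_CL"], tolerance = 0.02)
  expect_equal(emp[2, 2], fit$vcov["theta_Vc", "theta_Vc"], tolerance = 0.02)
})

test_that("missing vcov is a sampling error with advice to refit", {
  fit <- fit_small()
  fit$vcov <- NULL
  expect_error(sample_parameter_sets(fit), "refit with hessian")
})

test_that("exposure metrics behave like the closed forms in the linear model", {
  m <- lin_model()
  m$theta["CL"] <- 0.02  # half-life ~2 days: 25-day AUC nearly complete
  ref <- reference_subject()
  ex <- exposure_metrics(m, ref)
  dose <- 2500 * ref$BSA
  auc_inf <- dose / (m$theta[["CL"]] * 1000)
  expect_lt(ex$AUC0_25d, auc_inf)
  expect_equal(ex$AUC0_25d, auc_inf, tolerance = 2e-3)
  # truncation loss shrinks as the half-life shortens
  m2 <- m; m2$theta["CL"] <- 0.08
  ex2 <- exposure_metrics(m2, ref)
  auc_inf2 <- dose / (m2$theta[["CL"]] * 1000)
  expect_lt(abs(ex2$AUC0_25d - auc_inf2) / auc_inf2,
            abs(ex$AUC0_25d - auc_inf) / auc_inf)
  # doubling Vc halves Cmax (short-infusion limit)
  m2 <- m; m2$theta["Vc"] <- 2 * m$theta["Vc"]
  ex2 <- exposure_metrics(m2, ref, infusion_duration = 0.1)
  ex1 <- exposure_metrics(m, ref, infusion_duration = 0.1)
  expect_equal(ex1$Cmax / ex2$Cmax, 2, tolerance = 0.01)
})

test_that("grid AUC0-25d agrees with fine composite quadrature", {
  m <- default_model(bsv = FALSE)
  ref <- reference_subject()
  ex <- exposure_metrics(m, ref)
  pars <- apply_covariates(m, ref)
  doses <- data.frame(time = 0, amt = 2500 * ref$BSA, route = "IV", dur = 2,
                      dose_ordinal = 1)
  tq <- seq(0, 600, length.out = 10001)
  cq <- solve_activity(pars, doses, tq)
  orc <- sum((cq[-1] + cq[-length(cq)]) / 2 * diff(tq))
  expect_equal(ex$AUC0_25d, orc, tolerance = 1e-3)
})

test_that("the reference setting has ratio exactly 1 for every draw", {
  fit <- fit_small()
  ft <- forest_table(fit, list(reference = reference_subject()), n_draws = 25,
                     seed = 2)
  expect_equal(ft$ratio_median, c(1, 1))
  expect_equal(ft$ci_lo, c(1, 1))
  expect_equal(ft$ci_hi, c(1, 1))
  expect_true(all(ft$within_margins))
})

test_that("a pure -41% CL shift yields the closed-form AUC ratio 1/0.59", {
  m <- lin_model(beta_pop_cl = -0.41)
  m$theta["CL"] <- 0.05  # complete AUC within 25 days
  ft <- forest_table(m, list(japanese = ref_subject(POP = 1)))
  auc <- ft[ft$metric == "AUC0_25d", ]
  expect_equal(auc$ratio_median, 1 / 0.59, tolerance = 0.005)
})

test_that("a CL/Km-only population effect leaves Cmax inside the margins", {
  # saturated regime (Km well below Cmax), where a lower Km barely changes
  # the capacity-limited pathway while the lower CL raises exposure
  m <- pk_model(c(CL = 0.0067, Vc = 1.5, Vmax = 2, Km = 0.5),
                covariates = rbind(
    data.frame(param = c("CL", "Vc", "Vmax"), cov = "BSA", form = "power",
               value = 1),
    data.frame(param = c("CL", "Km"), cov = "POP", form = "frac",
               value = c(-0.41, -0.83))))
  ft <- forest_table(m, list(japanese = ref_subject(POP = 1)))
  cmax <- ft[ft$metric == "Cmax", ]
  expect_gt(cmax$ratio_median, 0.80)
  expect_lt(cmax$ratio_median, 1.25)
  # slower elimination -> higher exposure
  expect_gt(ft[ft$metric == "AUC0_25d", "ratio_median"], 1)
})

test_that("scaling vcov up weakly widens every 90% interval", {
  fit <- fit_small()
  s <- list(big = ref_subject(BSA = 1.4), small = ref_subject(BSA = 0.5))
  f1 <- forest_table(fit, s, n_draws = 100, seed = 4)
  fit2 <- fit
  fit2$vcov <- fit$vcov * 4
  f2 <- forest_table(fit2, s, n_draws = 100, seed = 4)
  expect_true(all(f2$ci_hi - f2$ci_lo >= f1$ci_hi - f1$ci_lo - 1e-10))
})

test_that("BSA-proportional clearance and dosing give AUC ratio 1 across BSA", {
  m <- lin_model()  # CL and Vc scale with BSA^1; dose = 2500*BSA
  ft <- forest_table(m, list(small = ref_subject(BSA = 0.5),
                             large = ref_subject(BSA = 1.5)))
  auc <- ft[ft$metric == "AUC0_25d", ]
  expect_equal(auc$ratio_median, c(1, 1), tolerance = 1e-10)
})
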