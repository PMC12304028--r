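test_that("covariate mapping is the identity at the reference patient", {
  m <- default_model()
  p <- apply_covariates(m, ref_subject())
  expect_equal(p[c("CL", "Vc", "Vmax", "Km")],
               m$theta[c("CL", "Vc", "Vmax", "Km")])
})

test_that("fractional population shifts scale CL and Km as specified", {
  m <- default_model()
  m$covariates <- rbind(m$covariates,
    data.frame(param = c("CL", "Km"), cov = "POP", form = "frac",
               value = c(-0.41, -0.83)))
  p <- apply_covariates(m, ref_subject(POP = 1))
  expect_equal(unname(p["CL"]), 0.59 * unname(m$theta["CL"]))
  expect_equal(unname(p["Km"]), 0.17 * unname(m$theta["Km"]))
  # non-Japanese unaffected
  p0 <- apply_covariates(m, ref_subject())
  expect_equal(unname(p0["CL"]), unname(m$theta["CL"]))
})

test_that("BSA power law: half the reference BSA with exponent 1 halves CL", {
  m <- default_model()
  p <- apply_covariates(m, ref_subject(BSA = 0.835 / 2))
  expect_equal(unname(p["CL"]), 0.5 * unname(m$theta["CL"]))
})

test_that("covariate mapping is homogeneous in BSA per the exponent", {
  m <- default_model()
  m$covariates$value <- c(0.75, 1, 0.6)  # CL, Vc, Vmax exponents
  for (bsa in c(0.5, 0.9, 1.4)) {
    p1 <- apply_covariates(m, ref_subject(BSA = bsa))
    p2 <- apply_covariates(m, ref_subject(BSA = 2 * bsa))
    expect_equal(unname(p2["CL"] / p1["CL"]), 2^0.75)
    expect_equal(unname(p2["Vc"] / p1["Vc"]), 2)
    expect_equal(unname(p2["Vmax"] / p1["Vmax"]), 2^0.6)
  }
})

test_that("invalid covariates and coefficients are rejected", {
  m <- default_model()
  expect_error(apply_covariates(m, ref_subject(BSA = -1)), "non-positive")
  expect_error(apply_covariates(m, ref_subject(BSA = NA)), "lacks|invalid")
  expect_error(pk_model(c(CL = 0.0067, Vc = 1.5, Vmax = 0, Km = 2),
                        covariates = data.frame(param = "CL", cov = "POP",
                                                form = "frac", value = -1)),
               "must be > -1")
})

test_that("closed-form infusion solution matches a quadrature oracle", {
  CL <- 0.0067; Vc <- 1.5; dose <- 2000; dur <- 2
  expect_equal(closed_form_linear_iv(CL, Vc, dose, dur, 0), 0)
  expect_lt(closed_form_linear_iv(CL, Vc, dose, dur, 1e6), 1e-6)
  # A(t) = int_0^min(t,TI) R0 exp(-k (t-s)) ds by numeric quadrature
  k <- CL / Vc
  for (t in c(1, 2, 48, 336)) {
    orc <- integrate(function(s) dose / dur * exp(-k * (t - s)), 0, min(t, dur),
                     rel.tol = 1e-13)$value / (Vc * 1000)
    expect_equal(closed_form_linear_iv(CL, Vc, dose, dur, t), orc,
                 tolerance = 1e-10)
  }
})

test_that("ODE solution matches the closed form in the linear limit", {
  p <- c(CL = 0.0067, Vc = 1.5, Vmax = 0, Km = 2)
  tt <- c(0, 0.5, 2, 4, 24, 96, 336, 600)
  ode <- solve_activity(p, one_dose(2000), tt, method = "ode")
  ana <- closed_form_linear_iv(p["CL"], p["Vc"], 2000, 2, tt)
  expect_lt(max(abs(ode - ana) / pmax(ana, 1e-12)), 1e-3)
  # near-instantaneous input approaches the bolus solution
  tt2 <- c(1, 24, 96, 336)
  ode2 <- solve_activity(p, one_dose(2000, dur = 1e-3), tt2, method = "ode")
  bol <- 2000 / (p["Vc"] * 1000) * exp(-(p["CL"] / p["Vc"]) * tt2)
  expect_lt(max(abs(ode2 - bol) / bol), 1e-3)
})

test_that("activity is zero before the first dose", {
  p <- c(CL = 0.0067, Vc = 1.5, Vmax = 5.74, Km = 2)
  expect_equal(solve_activity(p, one_dose(1700, time = 10), c(0, 2, 9.9)),
               c(0, 0, 0))
})

test_that("nonlinear solution agrees with a fine-step RK4 oracle on a 25-day grid", {
  p <- c(CL = 0.0067, Vc = 1.5, Vmax = 5.74, Km = 0.5)  # strongly saturable
  tt <- c(1, 2, 4, 24, 48, 96, 264, 336, 432, 600)
  got <- solve_activity(p, one_dose(2087.5), tt)
  orc <- rk4_mm_iv(p["CL"], p["Vc"], p["Vmax"], p["Km"], 2087.5, 2, tt, h = 0.02)
  expect_lt(max(abs(got - orc) / orc), 1e-4)
})

test_that("mass balance holds with elimination switched off", {
  p <- c(CL = 0, Vc = 1.5, Vmax = 0, Km = 2)
  ct <- solve_activity(p, one_dose(1700), c(5, 100, 600), method = "ode")
  expect_equal(ct * p["Vc"] * 1000, rep(1700, 3), ignore_attr = TRUE,
               tolerance = 1e-7)
})

test_that("activity is non-increasing after the last input ends", {
  p <- c(CL = 0.0067, Vc = 1.5, Vmax = 5.74, Km = 2)
  tt <- seq(2, 600, by = 2)
  ct <- solve_activity(p, one_dose(1700), tt)
  expect_true(all(diff(ct) <= 1e-12))
})

test_that("saturable pathway converges to linear clearance CL + Vmax/Km", {
  CL <- 0.0067; ratio <- 2.87     # Vmax/Km: ml/h, i.e. 0.00287 L/h
  Km <- 1e6; Vmax <- ratio * Km
  tt <- c(4, 48, 336, 600)
  nonlin <- solve_activity(c(CL = CL, Vc = 1.5, Vmax = Vmax, Km = Km),
                           one_dose(2000), tt)
  lin <- closed_form_linear_iv(CL + ratio / 1000, 1.5, 2000, 2, tt)
  expect_lt(max(abs(nonlin - lin) / lin), 0.005)
})

test_that("IM doses enter through the depot with first/later bioavailability", {
  p <- c(CL = 0.0067, Vc = 1.5, Vmax = 0, Km = 2, ka = 0.05,
         F_first = 0.8, F_later = 0.6)
  doses <- data.frame(time = c(0, 336), amt = 2000, route = "IM", dur = NA,
                      dose_ordinal = 1:2)
  ct <- solve_activity(p, doses, c(0, 336, 3000))
  expect_equal(ct[1], 0)
  # with no elimination all bioavailable amount ends centrally
  p0 <- c(CL = 0, Vc = 1.5, Vmax = 0, Km = 2, ka = 0.5,
          F_first = 0.8, F_later = 0.6)
  c_end <- solve_activity(p0, doses, 3000)
  expect_equal(c_end * 1.5 * 1000, 2000 * (0.8 + 0.6), tolerance = 1e-5,
               ignore_attr = TRUE)
})
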