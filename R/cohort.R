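## Synthetic trial cohort generator: protocol dosing, sampling schedules,
## covariate sampling and noisy observation of the structural model.

#' Protocol dose of pegaspargase
#'
#' 2500 IU/m^2 for subjects with BSA >= 0.6 m^2, otherwise 82.5 IU/kg; the
#' boundary BSA = 0.6 m^2 uses the per-m^2 rule.
#'
#' @param bsa body surface area (m^2); @param weight body weight (kg)
#' @return dose amount (IU), vectorised.
#' @export
assign_protocol_dose <- function(bsa, weight) {
  if (any(is.na(bsa)) || any(is.na(weight)))
    stop("dosing error: missing BSA or weight")
  ifelse(bsa >= 0.6, 2500 * bsa, 82.5 * weight)
}

#' Dose days and PK sampling offsets for a risk group and treatment phase
#'
#' Induction sampling: pre-dose, 5 min, 4, 24, 48 h and 4, 11, 14, 18, 25
#' days post dose. Re-induction sampling: pre-dose and 11, 14, 25 days.
#' SR/IR subjects receive 3 doses in total, HR subjects 8. Calendar
#' placement of the later doses is a configurable approximation of the
#' backbone-regimen phases (defaults documented in the vignette).
#'
#' @param risk_group `"SR"`, `"IR"` or `"HR"`.
#' @param phase `"induction"`, `"re-induction"` or `"completion"`.
#' @param dose_days optional numeric vector of calendar dose days
#'   (overrides the defaults; first entry is the induction dose).
#' @return list with `dose_times` (h from first dose, all doses of the
#'   regimen), `offsets` (sampling offsets, h, relative to a dose in the
#'   requested phase; pre-dose encoded as 0), and `n_doses`.
#' @export
make_schedule <- function(risk_group, phase = "induction", dose_days = NULL) {
  risk_group <- match.arg(risk_group, c("SR", "IR", "HR"))
  if (!phase %in% c("induction", "re-induction", "completion"))
    stop("schedule error: unknown phase '", phase, "'")
  if (is.null(dose_days))
    dose_days <- if (risk_group == "HR")
      c(12, 38, 64, 92, 120, 148, 204, 262) else c(12, 168, 259)
  dose_times <- (dose_days - dose_days[1]) * 24
  offsets <- switch(phase,
    "induction"    = c(0, 5 / 60, 4, 24, 48, 96, 264, 336, 432, 600),
    "re-induction" = c(0, 264, 336, 600),
    "completion"   = 0)
  list(dose_times = dose_times, offsets = offsets, n_doses = length(dose_times))
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the Phase 2 trial design: n = 26 subjects, BSA drawn
#' log-normally around a median of 0.68 m^2 (range-truncated), weight tied
#' to BSA by an allometric relation, one HR subject expected per cohort,
#' 2-h IV infusions, LLOQ 0.01 IU/ml.
#'
#' @param n_subjects cohort size.
#' @param model true `pk_model` generating the data.
#' @param prop_hr probability a subject is high-risk.
#' @param prop_japanese probability of the Japanese-population indicator
#'   (default 1: a Japan-only trial).
#' @param prop_ada baseline anti-drug-antibody positivity probability.
#' @param bsa_meanlog,bsa_sdlog,bsa_range log-normal BSA distribution and
#'   truncation range (m^2).
#' @param infusion_duration h; @param lloq IU/ml; @param seed integer.
#' @param phases which dose ordinals carry PK sampling: `"induction"`
#'   samples dose 1 with the rich schedule; `"all"` also samples the
#'   re-induction doses with the sparse schedule.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 26, model = default_model(),
                        prop_hr = 1 / 26, prop_japanese = 1, prop_ada = 0.15,
                        bsa_meanlog = log(0.68), bsa_sdlog = 0.30,
                        bsa_range = c(0.45, 1.80),
                        infusion_duration = 2, lloq = 0.01,
                        phases = c("induction", "all"), seed = 1L) {
  stopifnot(n_subjects >= 1, lloq >= 0, infusion_duration > 0)
  phases <- match.arg(phases)
  structure(as.list(environment()), class = "cohort_spec")
}

.draw_subjects <- function(spec) {
  n <- spec$n_subjects
  bsa <- exp(rnorm(n, spec$bsa_meanlog, spec$bsa_sdlog))
  bsa <- pmin(pmax(bsa, spec$bsa_range[1]), spec$bsa_range[2])
  ## allometric weight-for-BSA with mild scatter (median 15.8 kg at 0.68 m^2)
  wt <- 26.1 * bsa^1.3 * exp(rnorm(n, 0, 0.08))
  data.frame(
    ID = seq_len(n),
    AGE = round(pmax(1, 4.8 * (bsa / 0.68)^2.2 * exp(rnorm(n, 0, 0.25))), 1),
    BSA = round(bsa, 3), WT = round(wt, 1),
    SEX = rbinom(n, 1, 0.5),
    POP = rbinom(n, 1, spec$prop_japanese),
    ADA = rbinom(n, 1, spec$prop_ada),
    RISK = ifelse(runif(n) < spec$prop_hr, "HR", sample(c("SR", "IR"), n, TRUE)))
}

#' Simulate a protocol-faithful trial dataset
#'
#' Draws subjects, assigns BSA-thresholded doses, computes individual
#' parameters `P_i = P_typical exp(eta_i)` with diagonal log-normal
#' between-subject variability, solves the structural model, applies the
#' combined residual error `y = f (1 + eps_p) + eps_a` and censors below
#' the LLOQ (BLQ flag, DV withheld). Pre-first-dose samples are reported
#' as BLQ by construction (no drug present). Deterministic under the
#' spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return event-record data frame in the package's dataset dialect (see
#'   [write_dataset()]), one row per dose or observation.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- spec$model
  om <- model$omega[model$omega > 0]
  if (any(!is.finite(om))) stop("specification error: invalid omega")
  set.seed(spec$seed)
  subj <- .draw_subjects(spec)
  rows <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj[i, ]
    sched <- make_schedule(s$RISK, "induction")
    amt <- assign_protocol_dose(s$BSA, s$WT)
    doses <- data.frame(time = sched$dose_times, amt = amt, route = "IV",
                        dur = spec$infusion_duration,
                        dose_ordinal = seq_along(sched$dose_times))
    ## sampled doses: induction always; re-induction doses optionally
    samp <- data.frame(time = numeric(), predose = logical())
    off <- make_schedule(s$RISK, "induction")$offsets
    samp <- rbind(samp, data.frame(time = doses$time[1] + off, predose = off == 0))
    if (spec$phases == "all" && nrow(doses) > 1) {
      roff <- make_schedule(s$RISK, "re-induction")$offsets
      for (d in utils::tail(seq_len(nrow(doses)), 2)[utils::tail(seq_len(nrow(doses)), 2) > 1])
        samp <- rbind(samp, data.frame(time = doses$time[d] + roff, predose = roff == 0))
    }
    samp <- samp[order(samp$time, !samp$predose), ]
    pars <- apply_covariates(model, s)
    eta <- setNames(rnorm(length(om), 0, sqrt(om)), names(om))
    pars[names(om)] <- pars[names(om)] * exp(eta)
    f <- solve_activity(pars, doses, samp$time)
    f[samp$predose & samp$time <= doses$time[1]] <- 0
    dv <- f * (1 + rnorm(length(f), 0, model$sigma["prop"])) +
      rnorm(length(f), 0, model$sigma["add"])
    dv[f == 0] <- 0
    blq <- dv < spec$lloq
    obs <- data.frame(ID = s$ID, TIME = samp$time, AMT = NA_real_, DUR = NA_real_,
                      DV = ifelse(blq, NA_real_, signif(dv, 6)), EVID = 0L,
                      MDV = as.integer(blq), BLQ = as.integer(blq),
                      ROUTE = "IV", DOSENO = NA_integer_)
    dos <- data.frame(ID = s$ID, TIME = doses$time, AMT = doses$amt,
                      DUR = doses$dur, DV = NA_real_, EVID = 1L, MDV = 1L,
                      BLQ = 0L, ROUTE = doses$route, DOSENO = doses$dose_ordinal)
    both <- rbind(dos, obs)  # pre-dose samples sort before the dose row
    both <- both[order(both$TIME, both$EVID), ]
    for (cc in c("BSA", "WT", "SEX", "POP", "ADA", "RISK", "AGE")) both[[cc]] <- s[[cc]]
    rows[[i]] <- both
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
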