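# pegaspk

Population and non-compartmental pharmacokinetics of pegaspargase
(pegylated *E. coli* L-asparaginase) in pediatric acute lymphoblastic
leukemia, with the endpoint statistics of a Phase 2 trial analysis.

Pegaspargase is dosed as enzymatic activity (2500 IU/m² IV for subjects
with BSA ≥ 0.6 m², 82.5 IU/kg below) and monitored as plasma asparaginase
activity; an activity ≥ 0.1 IU/ml 14 days (336 h) after dosing is the
surrogate threshold for sustained asparagine depletion. The package is
aimed at pharmacometricians and trial statisticians who want the whole
chain — data generation, NCA, population estimation, covariate inference,
endpoints — as tested, reusable code.

At its core is a one-compartment model with parallel linear and
Michaelis–Menten elimination,

    dA/dt = input(t) + ka·A_d − (CL/Vc)·A − Vmax·C/(Km + C),   C = A/(1000·Vc)

with BSA power covariates and categorical fractional shifts on the
parameters, estimated by FOCE with interaction (conditional modes,
linearised marginal likelihood, variance–covariance matrix from the
numerical Hessian), a stepwise covariate search (forward ΔOFV > 3.84,
backward ΔOFV > 6.63, adaptive scope reduction), and forest-plot exposure
simulation (Cmax, AUC0–25d) from 250 draws of the estimate uncertainty
against the 0.80–1.25 margins. Because patient-level trial data are not
released, a protocol-faithful synthetic cohort generator
(`simulate_cohort()`) stands in for the study data and makes every stage
testable end to end.

## Worked example

```r
library(pegaspk)

d <- simulate_cohort(cohort_spec(seed = 2026))   # trial defaults, n = 26
att <- threshold_attainment(d)                   # >= 0.1 IU/ml at 336 h
sprintf("%d/%d = %.1f%% (95%% CI %.1f, %.1f)",
        att$n_attaining, att$n_evaluable, att$proportion,
        att$ci_lower, att$ci_upper)
#> "22/26 = 84.6% (95% CI 65.1, 95.6)"

nca <- nca_by_subject(d)
round(c(mean_cmax = mean(nca$Cmax), mean_thalf = mean(nca$t_half)), 2)
#> mean_cmax mean_thalf
#>      1.36     117.69

ci <- clopper_pearson(23, 23)                    # the trial's Part 2 counts
round(c(ci$lower, ci$upper), 1)
#> [1]  85.2 100.0
```

The simulated cohort attains the day-14 threshold in 22 of 26 subjects —
high but, unlike the real trial's 26/26, not universal: under 30%
between-subject variability a cohort-wide sweep is an improbable event
(see the methods vignette). Mean Cmax (≈1.4 IU/ml) and mean half-life
(≈120 h) reproduce the published dose-group magnitudes. The exact
binomial interval at the trial's own counts reproduces its printed
85.2–100.0% CI.

A population fit at pooled-study scale (200 subjects, half flagged
Japanese, true −41% population effect on CL) from
`analysis/03_fit_population.R` prints:

```
 forward-1    CL~POP 1.269921e+02                        included
 forward-1    Vc~POP 1.298928e-03 dropped from scope (irrelevant)
  backward    CL~POP 1.269921e+02                        retained
estimated population effect on CL: 41.2% lower (true -41%)
```

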