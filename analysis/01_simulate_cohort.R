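#!/usr/bin/env Rscript
# Step 1 — generate the synthetic trial.
#
# Emulates the Phase 2 design: 26 subjects, BSA-thresholded IV dosing
# (2500 IU/m^2 at BSA >= 0.6 m^2, else 82.5 IU/kg), rich induction PK
# sampling plus sparse re-induction sampling, log-normal between-subject
# variability and LLOQ censoring at 0.01 IU/ml. Writes the event-record
# dataset consumed by every later step.

library(pegaspk)

seed <- 2026L
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = seed)            # trial defaults, phases = "all"
dat <- simulate_cohort(spec)
write_dataset(dat, "results/cohort.csv")

n_sub <- length(unique(dat$ID))
n_obs <- sum(dat$EVID == 0)
n_blq <- sum(dat$BLQ == 1)
cat(sprintf("simulated %d subjects: %d observations (%d BLQ), %d dose records\n",
            n_sub, n_obs, n_blq, sum(dat$EVID == 1)))
cat(sprintf("BSA >= 0.6 m^2: %d subjects; BSA < 0.6 m^2: %d subjects\n",
            sum(tapply(dat$BSA, dat$ID, min) >= 0.6),
            sum(tapply(dat$BSA, dat$ID, min) < 0.6)))
cat("wrote results/cohort.csv\n")
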