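#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Builds (a) a study-sized primary-care diabetic cohort (n = 287) with the
# fibrosis-state structure reported for the source population (17% at
# LSM >= 8.1 kPa, 11% at >= 12.1, 3% cirrhosis, 64% MASLD among the
# non-fibrotic), and (b) a spectrum-shifted referral cohort whose fibrosis
# prevalence matches a secondary-care validation setting (105/218 = 48%).

library(bimast)

seed <- 20240927
dir.create("results", showWarnings = FALSE)

primary_spec <- cohort_spec(n = 287, seed = seed)
primary <- generate_cohort(primary_spec)
write_cohort(primary, "results/cohort_primary.csv")
message(sprintf("primary care cohort: n=%d, LSM>=8.1: %.1f%%, cirrhosis: %.1f%%",
                nrow(primary), 100 * mean(primary$lsm >= 8.1),
                100 * mean(primary$fibrosis_state == "cirrhosis")))

factor <- solve_spectrum_factor(cohort_spec(n = 2000, seed = seed + 1), 105 / 218)
referral <- generate_cohort(spectrum_shift(cohort_spec(n = 2000, seed = seed + 1),
                                           factor))
write_cohort(referral, "results/cohort_referral.csv")
message(sprintf("referral cohort (spectrum factor %.2f): n=%d, LSM>=8.1: %.1f%%",
                factor, nrow(referral), 100 * mean(referral$lsm >= 8.1)))
message("wrote results/cohort_primary.csv and results/cohort_referral.csv")
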