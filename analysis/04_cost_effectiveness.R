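#!/usr/bin/env Rscript
# Stage 4: decision-tree + Markov cost-utility analysis.
#
# Six screening strategies vs standard of care on the placeholder
# health-economic parameter set: base-case table (discounted life
# expectancy, QALYs gained, correct-diagnosis change, lifetime per-person
# cost, ICER), one-way sensitivity on the time horizon and key costs,
# a 500-draw probabilistic sensitivity analysis and the cost-effectiveness
# acceptability curve.

library(bimast)

seed <- 20240927
cfg <- default_econ_config()
big <- generate_cohort(cohort_spec(n = 50000, seed = seed + 2))
acc <- strategy_accuracy(big, truth_threshold = 8.1, seed = seed)
message("strategy accuracy entering the model:")
print(acc, digits = 3)

base <- run_cea(cfg, acc)
utils::write.csv(base, "results/cea_base_case.csv", row.names = FALSE)
message(sprintf("base case: all ICERs vs SOC below CET %.0f GBP/QALY: %s",
                cfg$cet,
                all(base$icer_vs_soc < cfg$cet, na.rm = TRUE)))
print(base[, c("strategy", "qalys_gained_vs_soc", "lifetime_cost_pp",
               "icer_vs_soc", "icer_status")], digits = 6)

# one-way sensitivity: horizon (lifetime -> 5 years) and decompensation cost
ow <- do.call(rbind, lapply(setdiff(acc$name, "SOC"), function(nm) {
  h <- one_way_sensitivity(cfg, acc, "horizon", c(5, 10, 20, 40), strategy = nm)
  h$strategy <- nm
  h$parameter <- "horizon"
  h
}))
ow_cost <- one_way_sensitivity(cfg, acc, "costs.DC",
                               cfg$costs$DC * c(0.5, 1, 2), strategy = "BIMAST")
ow_cost$strategy <- "BIMAST"
ow_cost$parameter <- "costs.DC"
utils::write.csv(rbind(ow, ow_cost), "results/one_way_sensitivity.csv",
                 row.names = FALSE)
h5 <- subset(ow, value == 5)
message(sprintf("strategies still cost-effective at a 5-year horizon: %s",
                paste(h5$strategy[h5$icer < cfg$cet], collapse = ", ")))

# probabilistic sensitivity analysis + CEAC
draws <- psa(cfg, acc, n_draws = 500, seed = seed)
utils::write.csv(draws, "results/psa_draws.csv", row.names = FALSE)
grid <- seq(0, 50000, by = 2500)
curve <- ceac(draws, grid)
utils::write.csv(curve, "results/ceac.csv", row.names = FALSE)
at_cet <- subset(curve, threshold == cfg$cet & probability > 0)
message("acceptability at the CET:")
print(at_cet, digits = 3)
message("wrote results/cea_base_case.csv, one_way_sensitivity.csv, psa_draws.csv, ceac.csv")
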