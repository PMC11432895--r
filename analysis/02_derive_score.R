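#!/usr/bin/env Rscript
# Stage 2: derive and internally validate the screening score.
#
# 2:1 split of the primary-care cohort; univariate screen of candidate
# predictors; logistic fit of significant fibrosis (LSM >= 8.1 kPa) on BMI
# and AST; calibration (Brier, Hosmer-Lemeshow), discrimination (AUROC with
# DeLong CI), Youden-optimal cut-off, and operating characteristics at the
# published probability cut-offs (0.063 significant, 0.102 advanced) in the
# held-out third. Run stage 1 first.

library(bimast)

seed <- 20240927
cohort <- read_cohort("results/cohort_primary.csv")
sp <- split_cohort(cohort, seed = seed)
der <- sp$derivation
val <- sp$validation
message(sprintf("split %d -> derivation %d / validation %d",
                nrow(cohort), nrow(der), nrow(val)))

outcome_der <- der$lsm >= 8.1
screen <- univariate_screen(der, outcome_der,
                            c("age", "bmi", "waist", "ast", "alt",
                              "platelets", "albumin"))
print(screen, digits = 3)

fit <- fit_logistic(der, c("bmi", "ast"), outcome_der)
message(sprintf("fitted score: %.3f*BMI + %.3f*AST %+.3f (logLik %.1f, %d iter)",
                fit$coefficients[["bmi"]], fit$coefficients[["ast"]],
                fit$coefficients[["(Intercept)"]], fit$log_likelihood,
                fit$n_iterations))

rows <- list()
note <- function(metric, cohort_name, value, lo = NA, hi = NA) {
  rows[[length(rows) + 1]] <<- data.frame(metric = metric,
                                          cohort = cohort_name,
                                          value = value, ci_low = lo,
                                          ci_high = hi)
}

predict_prob <- function(df) {
  stats::plogis(drop(cbind(1, df$bmi, df$ast) %*% fit$coefficients))
}

for (endpoint in c(8.1, 12.1)) {
  label <- if (endpoint == 8.1) "significant" else "advanced"
  cut <- if (endpoint == 8.1) 0.063 else 0.102
  for (part in c("derivation", "validation")) {
    df <- if (part == "derivation") der else val
    y <- df$lsm >= endpoint
    p <- predict_prob(df)
    roc <- roc_auroc(p, y)
    nm <- paste(part, label, sep = "_")
    note("auroc", nm, roc$auroc, roc$ci_low, roc$ci_high)
    note("brier", nm, brier_score(p, y))
    hl <- hosmer_lemeshow(p, as.numeric(y))
    note("hosmer_lemeshow_p", nm, hl$p_value)
    cs <- confusion_summary(y, classify(p, cut, "greater"))
    m <- diagnostic_metrics(cs)
    note(sprintf("sensitivity_at_%.3f", cut), nm, m$sensitivity)
    note(sprintf("specificity_at_%.3f", cut), nm, m$specificity)
    note(sprintf("ppv_at_%.3f", cut), nm, m$ppv)
    note(sprintf("npv_at_%.3f", cut), nm, m$npv)
    yj <- optimal_cutoff(roc)
    note("youden_optimal_probability_cutoff", nm, yj$threshold)
  }
}

report <- do.call(rbind, rows)
utils::write.csv(report, "results/derivation_report.csv", row.names = FALSE)
message("wrote results/derivation_report.csv")
print(subset(report, metric == "auroc"), digits = 3)
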