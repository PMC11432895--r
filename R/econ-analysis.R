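#' Per-strategy screening accuracy for the economic model
#'
#' Score-based strategies get their sensitivity and specificity measured
#' empirically by applying their rule to a cohort (truth: LSM >=
#' `truth_threshold`). Probabilistic strategies (US+LFTs, SOC) use their
#' stated fixed values; TE, being the reference standard here, is exact by
#' construction.
#'
#' @param cohort Cohort data.frame.
#' @param strategies List from [strategy_definitions()].
#' @param truth_threshold 8.1 or 12.1 kPa.
#' @param seed Seed (unused by deterministic rules).
#' @return Data.frame `name, sensitivity, specificity, test_cost`.
#' @export
strategy_accuracy <- function(cohort, strategies = strategy_definitions(),
                              truth_threshold = 8.1, seed = 1) {
  rows <- lapply(strategies, function(s) {
    if (s$kind == "score") {
      cs <- apply_strategy(cohort, s, truth_threshold, seed)
      data.frame(name = s$name, sensitivity = cs$sensitivity,
                 specificity = cs$specificity, test_cost = s$test_cost,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = s$name, sensitivity = s$sensitivity,
                 specificity = s$specificity, test_cost = s$test_cost,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Decision tree + Markov for one accuracy row.
run_strategy <- function(config, sens, spec, test_cost) {
  tree <- build_decision_tree(config$entry_prevalence, sens, spec,
                              test_cost, config$referral_cost)
  out <- run_markov(tree$initial, config, tree$upfront_cost_pp)
  out$correct_diagnosis_rate <- tree$correct_diagnosis_rate
  out
}

#' Base-case cost-utility analysis of all screening strategies
#'
#' Runs the decision tree plus Markov model for every strategy in the
#' accuracy table (which must include a `SOC` row) and reports, per
#' strategy: discounted life expectancy for the whole cohort, cohort QALYs
#' gained versus SOC, the percentage-point increase in correct diagnoses,
#' lifetime discounted per-person cost, and the ICER versus SOC (with
#' dominance flags).
#'
#' @param config An `econ_config`.
#' @param accuracy Data.frame from [strategy_accuracy()].
#' @return Data.frame, one row per strategy (SOC included with empty
#'   incremental columns).
#' @export
run_cea <- function(config, accuracy) {
  validate_econ_config(config, check_ordering = FALSE)
  if (!"SOC" %in% accuracy$name) {
    stop("accuracy table must include a SOC row", call. = FALSE)
  }
  runs <- lapply(seq_len(nrow(accuracy)), function(i) {
    run_strategy(config, accuracy$sensitivity[i], accuracy$specificity[i],
                 accuracy$test_cost[i])
  })
  names(runs) <- accuracy$name
  soc <- runs[["SOC"]]
  rows <- lapply(accuracy$name, function(nm) {
    r <- runs[[nm]]
    inc <- icer(r, soc)
    data.frame(
      strategy = nm,
      discounted_life_years_cohort = r$life_years_cohort,
      qalys_cohort = r$qalys_cohort,
      qalys_gained_vs_soc = if (nm == "SOC") NA_real_ else
        r$qalys_cohort - soc$qalys_cohort,
      correct_diagnosis_rate = r$correct_diagnosis_rate,
      correct_diagnosis_increase_pct = if (nm == "SOC") NA_real_ else
        100 * (r$correct_diagnosis_rate - soc$correct_diagnosis_rate),
      lifetime_cost_pp = r$cost_pp,
      icer_vs_soc = if (nm == "SOC") NA_real_ else inc$icer,
      icer_status = if (nm == "SOC") "reference" else inc$status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full decision tree + Markov pipeline for one strategy across
#' a grid of values of a single parameter, all else fixed, and returns the
#' ICER versus SOC at each grid point. The parameter is addressed by a
#' dot-separated path into the config (e.g. `"discount_rate"`, `"horizon"`,
#' `"costs.DC"`, `"transitions.SLD_fn.CC_fn"`, `"utilities.DC"`).
#' Probability and utility values outside [0, 1] are rejected with the
#' violated bound named.
#'
#' @param config An `econ_config`.
#' @param accuracy Data.frame from [strategy_accuracy()].
#' @param parameter Dot-separated parameter path.
#' @param values Numeric grid.
#' @param strategy Strategy name to report (default `"BIMAST"`).
#' @return Data.frame `value, icer, icer_status`, sorted by value.
#' @export
one_way_sensitivity <- function(config, accuracy, parameter, values,
                                strategy = "BIMAST") {
  root <- strsplit(parameter, ".", fixed = TRUE)[[1]][1]
  if (root %in% c("transitions", "utilities", "soc_lfts_share")) {
    if (any(values < 0 | values > 1)) {
      stop("sensitivity range for '", parameter,
           "' violates the bound [0,1]", call. = FALSE)
    }
  }
  if (root %in% c("costs", "referral_cost", "horizon", "cohort_size") &&
      any(values < 0)) {
    stop("sensitivity range for '", parameter,
         "' violates the bound >= 0", call. = FALSE)
  }
  rows <- lapply(sort(values), function(v) {
    cfg <- set_config_value(config, parameter, v)
    validate_econ_config(cfg, check_ordering = FALSE)
    res <- run_cea(cfg, accuracy)
    i <- match(strategy, res$strategy)
    data.frame(value = v, icer = res$icer_vs_soc[i],
               icer_status = res$icer_status[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One joint PSA parameter draw. Probabilities and utilities are drawn from
# beta distributions centred on the base case with effective sample size
# n_eff (n_eff = Inf, or a base value of exactly 0 or 1, is degenerate);
# state and referral costs from gamma distributions with coefficient of
# variation cost_cv (0 = degenerate). Off-diagonal transition rows are
# rescaled if a draw pushes their sum above 1.
draw_psa_config <- function(config) {
  rbeta_mean <- function(m, n_eff) {
    if (!is.finite(n_eff) || m <= 0 || m >= 1) return(m)
    stats::rbeta(1, m * n_eff, (1 - m) * n_eff)
  }
  rgamma_mean <- function(m, cv) {
    if (cv <= 0 || m <= 0) return(m)
    stats::rgamma(1, shape = 1 / cv^2, scale = m * cv^2)
  }
  psa <- config$psa
  cfg <- config
  for (st in setdiff(econ_states(), "DEAD")) {
    tr <- cfg$transitions[[st]]
    for (to in names(tr)) {
      tr[[to]] <- rbeta_mean(config$transitions[[st]][[to]],
                             psa$n_eff_probabilities)
    }
    tot <- sum(unlist(tr))
    if (tot > 1) tr <- lapply(tr, function(p) p / tot)
    cfg$transitions[[st]] <- tr
  }
  for (st in econ_states()) {
    cfg$utilities[[st]] <- rbeta_mean(config$utilities[[st]],
                                      psa$n_eff_utilities)
    cfg$costs[[st]] <- rgamma_mean(config$costs[[st]], psa$cost_cv)
  }
  cfg$referral_cost <- rgamma_mean(config$referral_cost, psa$cost_cv)
  cfg
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter sets (beta for probabilities and
#' utilities, gamma for costs, hyper-parameters from `config$psa`) and
#' re-runs the decision tree + Markov model for every strategy on each draw
#' (common random numbers: one parameter set per draw shared by all
#' strategies). Deterministic given the seed.
#'
#' @param config An `econ_config`.
#' @param accuracy Data.frame from [strategy_accuracy()].
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Data.frame `draw, strategy, cost_pp, qaly_pp`.
#' @export
psa <- function(config, accuracy, n_draws, seed = 1) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("n_draws must be >= 1", call. = FALSE)
  }
  validate_econ_config(config, check_ordering = FALSE)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_draws), function(d) {
      cfg <- draw_psa_config(config)
      res <- lapply(seq_len(nrow(accuracy)), function(i) {
        run_strategy(cfg, accuracy$sensitivity[i], accuracy$specificity[i],
                     accuracy$test_cost[i])
      })
      data.frame(draw = d, strategy = accuracy$name,
                 cost_pp = vapply(res, `[[`, numeric(1), "cost_pp"),
                 qaly_pp = vapply(res, `[[`, numeric(1), "qalys_pp"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that a strategy is
#' cost-effective is the fraction of PSA draws in which its net monetary
#' benefit (threshold x QALY - cost) is the largest among the compared
#' strategies; the probabilities sum to 1 at every threshold.
#'
#' @param psa_draws Data.frame from [psa()].
#' @param thresholds Sorted numeric grid of thresholds (GBP/QALY), non-empty.
#' @return Data.frame `threshold, strategy, probability`.
#' @export
ceac <- function(psa_draws, thresholds) {
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  strategies <- unique(psa_draws$strategy)
  draws <- unique(psa_draws$draw)
  # reshape: rows = strategy, cols = draw (input is blocked per draw)
  qal <- matrix(psa_draws$qaly_pp, nrow = length(strategies))
  cst <- matrix(psa_draws$cost_pp, nrow = length(strategies))
  rows <- lapply(thresholds, function(lambda) {
    nmb <- lambda * qal - cst
    winner <- apply(nmb, 2, which.max)
    data.frame(threshold = lambda, strategy = strategies,
               probability = tabulate(winner, nbins = length(strategies)) /
                 length(draws),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
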