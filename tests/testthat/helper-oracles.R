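# Independent oracles and small fixture builders shared across tests.

# Brute-force AUROC: exhaustive concordant-pair count with ties worth 1/2.
auc_brute_force <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  s1 <- scores[y]
  s0 <- scores[!y]
  (sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))) /
    (length(s1) * length(s0))
}

# Brute-force Mann-Whitney U for group a vs group b: count pairs where
# a > b, ties 1/2.
u_brute_force <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# A tiny hand-built cohort satisfying every record invariant.
tiny_cohort <- function(n = 10, seed = 99) {
  generate_cohort(cohort_spec(n = n, seed = seed))
}

# Random valid econ config: jitter the packaged placeholder while keeping
# probabilities in [0,1], off-diagonal row sums < 1 and the fn >= dx
# progression ordering (multiplicative jitter preserves ordering when the
# same factor applies within a row pair family; we jitter rows and rescale).
random_econ_config <- function(base = default_econ_config()) {
  cfg <- base
  for (st in setdiff(econ_states(), "DEAD")) {
    tr <- cfg$transitions[[st]]
    for (to in names(tr)) {
      tr[[to]] <- min(1, tr[[to]] * stats::runif(1, 0.5, 1.5))
    }
    tot <- sum(unlist(tr))
    if (tot >= 1) tr <- lapply(tr, function(p) 0.95 * p / tot)
    cfg$transitions[[st]] <- tr
  }
  for (st in econ_states()) {
    cfg$utilities[[st]] <- min(1, max(0, cfg$utilities[[st]] *
                                        stats::runif(1, 0.8, 1.1)))
    cfg$costs[[st]] <- cfg$costs[[st]] * stats::runif(1, 0.5, 2)
  }
  # restore the model's core assumption after jitter: missed diagnoses
  # progress and die at least as fast, and fare no better, than diagnosed
  cfg$transitions$SLD_fn$CC_fn <- max(cfg$transitions$SLD_fn$CC_fn,
                                      cfg$transitions$SLD_dx$CC_dx)
  cfg$transitions$SLD_fn$DEAD <- max(cfg$transitions$SLD_fn$DEAD,
                                     cfg$transitions$SLD_dx$DEAD)
  cfg$transitions$CC_fn$DC <- max(cfg$transitions$CC_fn$DC,
                                  cfg$transitions$CC_dx$DC)
  cfg$transitions$CC_fn$HCC <- max(cfg$transitions$CC_fn$HCC,
                                   cfg$transitions$CC_dx$HCC)
  cfg$transitions$CC_fn$DEAD <- max(cfg$transitions$CC_fn$DEAD,
                                    cfg$transitions$CC_dx$DEAD)
  cfg$utilities$SLD_fn <- min(cfg$utilities$SLD_fn, cfg$utilities$SLD_dx)
  cfg$utilities$CC_fn <- min(cfg$utilities$CC_fn, cfg$utilities$CC_dx)
  cfg$utilities$DEAD <- 0
  cfg$discount_rate <- stats::runif(1, 0, 0.08)
  cfg$horizon <- sample(5:60, 1)
  cfg
}

# Closed-form per-cycle discounting oracle: recompute a Markov run's
# discounted totals by explicit per-cycle products from the trace.
discounted_totals_oracle <- function(trace, config) {
  states <- econ_states()
  util <- unlist(config$utilities[states])
  cost <- unlist(config$costs[states])
  alive <- states != "DEAD"
  r <- config$discount_rate
  H <- config$horizon
  ly <- qaly <- cst <- 0
  for (t in 0:(H - 1)) {
    disc <- prod(rep(1 / (1 + r), t))
    occ <- trace[t + 1, ]
    ly <- ly + disc * sum(occ[alive])
    qaly <- qaly + disc * sum(occ * util)
    cst <- cst + disc * sum(occ * cost)
  }
  list(life_years = ly, qalys = qaly, cost = cst)
}
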