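#' Decision tree: initial state distribution and upfront costs for a strategy
#'
#' Risk stratification at screening: diseased subjects (SLD or CC at entry)
#' who test positive enter the diagnosed states (`SLD_dx`/`CC_dx`); diseased
#' subjects who test negative enter the false-negative states
#' (`SLD_fn`/`CC_fn`) and progress at the faster, undiagnosed rates.
#' Non-diseased subjects stay in MLD; the false-positive fraction
#' (1 - specificity) incurs a one-off specialist referral cost. The upfront
#' per-person cost is the test cost plus the referral cost times the
#' probability of a positive test.
#'
#' @param prevalence Named proportions over `MLD`, `SLD`, `CC`, summing to 1.
#' @param sens,spec Test sensitivity and specificity in [0, 1].
#' @param test_cost GBP per person screened.
#' @param referral_cost GBP per positive test (specialist review).
#' @return List: `initial` (named distribution over [econ_states()], sums to
#'   1), `upfront_cost_pp` (GBP/person), `correct_diagnosis_rate`.
#' @export
build_decision_tree <- function(prevalence, sens, spec,
                                test_cost = 0, referral_cost = 0) {
  pv <- unlist(prevalence[c("MLD", "SLD", "CC")])
  if (length(pv) != 3 || any(is.na(pv)) || any(pv < 0) ||
      abs(sum(pv) - 1) > 1e-9) {
    stop("malformed prevalence: need MLD/SLD/CC proportions summing to 1",
         call. = FALSE)
  }
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) {
    stop("sens and spec must lie in [0,1]", call. = FALSE)
  }
  init <- stats::setNames(numeric(length(econ_states())), econ_states())
  init["MLD"] <- pv["MLD"]
  init["SLD_dx"] <- pv["SLD"] * sens
  init["SLD_fn"] <- pv["SLD"] * (1 - sens)
  init["CC_dx"] <- pv["CC"] * sens
  init["CC_fn"] <- pv["CC"] * (1 - sens)
  diseased <- unname(pv["SLD"] + pv["CC"])
  positives <- sens * diseased + (1 - spec) * unname(pv["MLD"])
  list(initial = init,
       upfront_cost_pp = test_cost + referral_cost * positives,
       correct_diagnosis_rate = unname(sens * diseased + spec * pv["MLD"]))
}

#' Run the Markov cohort model
#'
#' Annual cycles over the configured horizon. Life-years, QALYs and costs
#' accrue on the occupancy at the start of each cycle, discounted by
#' (1 + discount_rate)^-t with t = 0 for the first cycle; occupancy is then
#' advanced through the transition matrix. With
#' `half_cycle_correction: true` in the config, the first and the
#' post-horizon occupancies receive half weight instead. The occupancy
#' vector sums to 1 at every cycle.
#'
#' @param initial Named distribution over [econ_states()] summing to 1.
#' @param config An `econ_config`.
#' @param upfront_cost_pp One-off screening/referral cost, GBP per person,
#'   added undiscounted at t = 0.
#' @return List: `trace` ((horizon+1) x 9 occupancy matrix),
#'   `life_years_pp`, `qalys_pp`, `cost_pp` (discounted, per person) and
#'   cohort totals `life_years_cohort`, `qalys_cohort`, `cost_cohort`.
#' @export
run_markov <- function(initial, config, upfront_cost_pp = 0) {
  states <- econ_states()
  P <- build_transition_matrix(config)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("transition matrix is not row-stochastic", call. = FALSE)
  }
  occ <- unlist(initial[states])
  if (any(is.na(occ)) || abs(sum(occ) - 1) > 1e-9) {
    stop("initial distribution must cover all states and sum to 1",
         call. = FALSE)
  }
  H <- config$horizon
  r <- config$discount_rate
  util <- unlist(config$utilities[states])
  cost <- unlist(config$costs[states])
  alive <- states != "DEAD"
  hcc <- isTRUE(config$half_cycle_correction)
  trace <- matrix(NA_real_, nrow = H + 1, ncol = length(states),
                  dimnames = list(NULL, states))
  ly <- qaly <- cst <- 0
  for (t in 0:H) {
    trace[t + 1, ] <- occ
    w <- if (hcc && (t == 0 || t == H)) 0.5 else if (t == H) 0 else 1
    if (w > 0) {
      disc <- (1 + r)^(-t)
      ly <- ly + w * disc * sum(occ[alive])
      qaly <- qaly + w * disc * sum(occ * util)
      cst <- cst + w * disc * sum(occ * cost)
    }
    if (t < H) occ <- drop(occ %*% P)
  }
  cst <- cst + upfront_cost_pp
  N <- config$cohort_size
  list(trace = trace, life_years_pp = ly, qalys_pp = qaly, cost_pp = cst,
       life_years_cohort = ly * N, qalys_cohort = qaly * N,
       cost_cohort = cst * N)
}

#' Incremental cost-effectiveness ratio versus standard of care
#'
#' ICER = (cost difference) / (QALY difference), per person (equivalently
#' cohort totals, which scale identically). Strategies that gain QALYs while
#' saving money are flagged `dominant`; strategies that lose QALYs at extra
#' cost are flagged `dominated`; a zero QALY difference yields `undefined`.
#'
#' @param strategy_outcome,soc_outcome Results of [run_markov()] produced
#'   under identical config and horizon.
#' @return List `icer` (GBP/QALY or NA), `status`
#'   (`"icer"`, `"dominant"`, `"dominated"`, `"undefined"`),
#'   `delta_cost_pp`, `delta_qaly_pp`.
#' @export
icer <- function(strategy_outcome, soc_outcome) {
  dc <- strategy_outcome$cost_pp - soc_outcome$cost_pp
  dq <- strategy_outcome$qalys_pp - soc_outcome$qalys_pp
  if (dq == 0) {
    status <- "undefined"
    value <- NA_real_
  } else if (dq > 0 && dc < 0) {
    status <- "dominant"
    value <- NA_real_
  } else if (dq < 0 && dc > 0) {
    status <- "dominated"
    value <- NA_real_
  } else {
    status <- "icer"
    value <- dc / dq
  }
  list(icer = value, status = status, delta_cost_pp = dc, delta_qaly_pp = dq)
}
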