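#' Markov model state labels
#'
#' Nine states: mild/no liver disease (MLD), significant/advanced liver
#' disease and compensated cirrhosis each split by whether the diagnosis was
#' made at screening (`_dx`) or missed (`_fn`, false negative), plus
#' decompensated cirrhosis (DC), hepatocellular carcinoma (HCC), liver
#' transplant (LT) and DEAD. Splitting dx/fn makes "slower progression when
#' diagnosed" a parameter rather than a special case.
#' @export
econ_states <- function() {
  c("MLD", "SLD_dx", "SLD_fn", "CC_dx", "CC_fn", "DC", "HCC", "LT", "DEAD")
}

#' Load a health-economic configuration from YAML
#'
#' The file carries annual transition probabilities (off-diagonal; each
#' state's self-transition is the remainder), state costs (GBP/year), state
#' utilities (QALY weight/year), test/referral costs (GBP), discount rate,
#' horizon (years), cohort size, cost-effectiveness threshold, entry
#' prevalence over MLD/SLD/CC, the SOC composition, and PSA distribution
#' hyper-parameters. The schema is validated on load.
#'
#' @param path YAML file; defaults to the packaged placeholder parameter set
#'   (plausible values satisfying every structural invariant, not the
#'   study's supplementary tables).
#' @return Object of class `econ_config`.
#' @export
read_econ_config <- function(path = system.file("extdata",
                                                "econ_placeholder.yaml",
                                                package = "bimast")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("econ config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg <- structure(cfg, class = "econ_config")
  validate_econ_config(cfg)
  cfg
}

#' Default (placeholder) health-economic configuration
#'
#' @return The packaged placeholder `econ_config`.
#' @export
default_econ_config <- function() {
  read_econ_config()
}

#' Validate an econ_config
#'
#' Checks: every probability in [0,1]; off-diagonal row sums <= 1 (so rows
#' of the implied matrix sum to 1 exactly); DEAD absorbing; utilities in
#' [0,1]; undiagnosed (fn) progression probabilities at least the diagnosed
#' counterparts, state-by-state; costs non-negative; discount rate, horizon,
#' cohort size, entry prevalence well-formed.
#'
#' @param config An `econ_config`.
#' @param check_ordering Check the fn >= dx progression ordering (disabled
#'   for probabilistic sensitivity draws, which explore around it).
#' @return The config, invisibly; stops with the offending field otherwise.
#' @export
validate_econ_config <- function(config, check_ordering = TRUE) {
  states <- econ_states()
  req <- c("transitions", "costs", "utilities", "referral_cost",
           "discount_rate", "horizon", "cohort_size", "cet",
           "entry_prevalence", "soc_lfts_share", "psa")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f)) {
    stop("econ config missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  for (st in setdiff(states, "DEAD")) {
    tr <- config$transitions[[st]]
    if (is.null(tr)) stop("econ config: missing transitions for state ", st,
                          call. = FALSE)
    bad <- setdiff(names(tr), states)
    if (length(bad)) stop("econ config: unknown destination state '", bad[1],
                          "' from ", st, call. = FALSE)
    pr <- unlist(tr)
    if (any(pr < 0 | pr > 1)) {
      stop("econ config: transition probability out of [0,1] from ", st,
           call. = FALSE)
    }
    if (sum(pr) > 1 + 1e-12) {
      stop("econ config: transitions from ", st, " exceed 1", call. = FALSE)
    }
  }
  if (!is.null(config$transitions$DEAD) &&
      length(unlist(config$transitions$DEAD)) > 0) {
    stop("econ config: DEAD must be absorbing", call. = FALSE)
  }
  for (st in states) {
    u <- config$utilities[[st]]
    if (is.null(u) || u < 0 || u > 1) {
      stop("econ config: utility for ", st, " missing or outside [0,1]",
           call. = FALSE)
    }
    cst <- config$costs[[st]]
    if (is.null(cst) || cst < 0) {
      stop("econ config: cost for ", st, " missing or negative", call. = FALSE)
    }
  }
  if (check_ordering) {
    get_p <- function(from, to) {
      p <- config$transitions[[from]][[to]]
      if (is.null(p)) 0 else p
    }
    pairs <- list(
      c("SLD_fn", "CC_fn", "SLD_dx", "CC_dx"),
      c("SLD_fn", "DEAD", "SLD_dx", "DEAD"),
      c("CC_fn", "DC", "CC_dx", "DC"),
      c("CC_fn", "HCC", "CC_dx", "HCC"),
      c("CC_fn", "DEAD", "CC_dx", "DEAD")
    )
    for (pr in pairs) {
      if (get_p(pr[1], pr[2]) < get_p(pr[3], pr[4]) - 1e-12) {
        stop("econ config: undiagnosed progression ", pr[1], "->", pr[2],
             " must be >= diagnosed counterpart ", pr[3], "->", pr[4],
             call. = FALSE)
      }
    }
  }
  if (config$discount_rate < 0) stop("econ config: negative discount_rate",
                                     call. = FALSE)
  if (config$horizon < 1) stop("econ config: horizon must be >= 1 year",
                               call. = FALSE)
  if (config$cohort_size <= 0) stop("econ config: cohort_size must be positive",
                                    call. = FALSE)
  ep <- unlist(config$entry_prevalence[c("MLD", "SLD", "CC")])
  if (length(ep) != 3 || any(is.na(ep)) || any(ep < 0) ||
      abs(sum(ep) - 1) > 1e-12) {
    stop("econ config: entry_prevalence must give MLD/SLD/CC summing to 1",
         call. = FALSE)
  }
  if (config$soc_lfts_share < 0 || config$soc_lfts_share > 1) {
    stop("econ config: soc_lfts_share must lie in [0,1]", call. = FALSE)
  }
  invisible(config)
}

#' Build the full annual transition matrix from a config
#'
#' Off-diagonal entries come from the config; each diagonal is the remainder
#' so every row sums to exactly 1. DEAD is absorbing.
#'
#' @param config An `econ_config`.
#' @return 9x9 row-stochastic matrix over [econ_states()].
#' @export
build_transition_matrix <- function(config) {
  states <- econ_states()
  P <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (st in setdiff(states, "DEAD")) {
    tr <- config$transitions[[st]]
    for (to in names(tr)) P[st, to] <- tr[[to]]
    P[st, st] <- P[st, st] + (1 - sum(unlist(tr)))
  }
  P["DEAD", "DEAD"] <- 1
  P
}

# Set a nested config value via a dot-separated path, e.g. "costs.DC" or
# "transitions.SLD_fn.CC_fn" or "discount_rate".
set_config_value <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- config
  for (p in parts[-length(parts)]) {
    if (is.null(ref[[p]])) stop("unknown parameter path: ", path, call. = FALSE)
    ref <- ref[[p]]
  }
  if (is.null(ref[[parts[length(parts)]]])) {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  config[[parts]] <- value
  config
}
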