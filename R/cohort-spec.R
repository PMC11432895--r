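#' Fibrosis-state labels used throughout the package
#'
#' Four mutually exclusive states defined by liver stiffness (LSM, kPa):
#' `none_or_mild` (< 8.1), `significant` (8.1-12.0), `advanced`
#' (12.1-25.0, non-cirrhotic) and `cirrhosis` (> 25).
#' @export
fibrosis_states <- function() {
  c("none_or_mild", "significant", "advanced", "cirrhosis")
}

# Biomarkers generated for every subject, in the order used by the copula.
cohort_biomarkers <- function() {
  c("age", "bmi", "waist", "ast", "alt", "platelets", "albumin", "elf", "lsm")
}

# LSM ranges (kPa) are disjoint per state so labels and stiffness thresholds
# can never disagree.
lsm_state_ranges <- function() {
  list(
    none_or_mild = c(2.0, 8.0),
    significant  = c(8.1, 12.0),
    advanced     = c(12.1, 25.0),
    cirrhosis    = c(25.1, 75.0)
  )
}

#' Default per-state biomarker marginals
#'
#' Location/scale parameters for each biomarker conditional on fibrosis state.
#' Locations are medians on the natural scale. BMI, waist, age, platelets,
#' albumin and ELF use truncated normals; AST, ALT and LSM use (truncated)
#' log-normals, reflecting the right skew of liver enzymes and stiffness.
#' The mixture medians across the three fibrotic states (weights 6:8:3)
#' reproduce the published primary-care group medians: BMI 36.8 vs 30.3 kg/m2,
#' AST 37 vs 26 IU/L, waist 120 vs 105 cm.
#'
#' @return Nested list: `group_params[[state]][[biomarker]]` with fields
#'   `dist` ("tnorm" or "lnorm"), `location` (median), `scale` (sd on natural
#'   scale for tnorm, sdlog for lnorm) and `range` (truncation bounds).
#' @export
default_group_params <- function() {
  tn <- function(location, scale, lo, hi) {
    list(dist = "tnorm", location = location, scale = scale, range = c(lo, hi))
  }
  ln <- function(location, sdlog, lo, hi) {
    list(dist = "lnorm", location = location, scale = sdlog, range = c(lo, hi))
  }
  rng <- lsm_state_ranges()
  list(
    none_or_mild = list(
      age = tn(58, 10, 25, 90), bmi = tn(30.3, 5.5, 17, 70),
      waist = tn(105, 12, 60, 200), ast = ln(26, 0.35, 5, 400),
      alt = ln(28, 0.45, 5, 500), platelets = tn(250, 60, 30, 600),
      albumin = tn(44, 3.5, 20, 55), elf = tn(9.0, 0.7, 6, 14),
      lsm = ln(5.0, 0.5, rng$none_or_mild[1], rng$none_or_mild[2])
    ),
    significant = list(
      age = tn(60, 10, 25, 90), bmi = tn(35.8, 5.5, 17, 70),
      waist = tn(117, 12, 60, 200), ast = ln(34, 0.35, 5, 400),
      alt = ln(36, 0.45, 5, 500), platelets = tn(240, 60, 30, 600),
      albumin = tn(43, 3.5, 20, 55), elf = tn(9.7, 0.7, 6, 14),
      lsm = ln(9.8, 0.5, rng$significant[1], rng$significant[2])
    ),
    advanced = list(
      age = tn(62, 10, 25, 90), bmi = tn(37.2, 5.5, 17, 70),
      waist = tn(122, 12, 60, 200), ast = ln(39, 0.35, 5, 400),
      alt = ln(40, 0.45, 5, 500), platelets = tn(220, 60, 30, 600),
      albumin = tn(42, 3.5, 20, 55), elf = tn(10.1, 0.7, 6, 14),
      lsm = ln(15.0, 0.5, rng$advanced[1], rng$advanced[2])
    ),
    cirrhosis = list(
      age = tn(64, 10, 25, 90), bmi = tn(38.5, 5.5, 17, 70),
      waist = tn(126, 12, 60, 200), ast = ln(46, 0.35, 5, 400),
      alt = ln(40, 0.45, 5, 500), platelets = tn(170, 60, 30, 600),
      albumin = tn(39, 3.5, 20, 55), elf = tn(10.9, 0.7, 6, 14),
      lsm = ln(33.0, 0.5, rng$cirrhosis[1], rng$cirrhosis[2])
    )
  )
}

#' Default latent rank-correlation targets between biomarkers
#'
#' Correlation matrix of the latent Gaussian copula. Anthropometric pairs
#' (BMI-waist) and enzyme pairs (AST-ALT) are strongly coupled; stiffness
#' correlates positively with enzymes and ELF and negatively with platelets
#' and albumin (portal hypertension / synthetic function).
#' @export
default_correlation <- function() {
  v <- cohort_biomarkers()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_cor <- function(R, a, b, r) {
    R[a, b] <- r; R[b, a] <- r; R
  }
  R <- set_cor(R, "bmi", "waist", 0.80)
  R <- set_cor(R, "ast", "alt", 0.70)
  R <- set_cor(R, "elf", "lsm", 0.40)
  R <- set_cor(R, "age", "elf", 0.30)
  R <- set_cor(R, "bmi", "ast", 0.20)
  R <- set_cor(R, "waist", "ast", 0.18)
  R <- set_cor(R, "bmi", "lsm", 0.20)
  R <- set_cor(R, "waist", "lsm", 0.18)
  R <- set_cor(R, "ast", "lsm", 0.30)
  R <- set_cor(R, "alt", "lsm", 0.20)
  R <- set_cor(R, "platelets", "lsm", -0.20)
  R <- set_cor(R, "albumin", "lsm", -0.20)
  R
}

#' Construct a cohort-generation specification
#'
#' Bundles everything [generate_cohort()] needs: cohort size, fibrosis-state
#' prevalences, steatosis (MASLD) prevalence among non-fibrotic subjects,
#' per-state biomarker marginals, copula correlation, spectrum-shift factor
#' and RNG seed. Default prevalences place 17% of subjects at LSM >= 8.1 kPa
#' (6% significant-only + 8% advanced + 3% cirrhosis) and 11% at
#' LSM >= 12.1 kPa, matching the primary-care study population.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Integer RNG seed; identical specs generate identical cohorts.
#' @param prevalence Named numeric over [fibrosis_states()], summing to 1.
#' @param masld_prevalence MASLD probability among non-fibrotic subjects;
#'   fibrotic subjects are always MASLD (the score concerns MASLD fibrosis).
#' @param group_params Per-state marginals, see [default_group_params()].
#' @param correlation Latent copula correlation, see [default_correlation()].
#' @param spectrum_shift Non-negative severity enrichment factor; 0 is the
#'   primary-care population. See [spectrum_shift()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        seed,
                        prevalence = c(none_or_mild = 0.83, significant = 0.06,
                                       advanced = 0.08, cirrhosis = 0.03),
                        masld_prevalence = 0.64,
                        group_params = default_group_params(),
                        correlation = default_correlation(),
                        spectrum_shift = 0) {
  spec <- structure(
    list(n = n, seed = seed, prevalence = prevalence,
         masld_prevalence = masld_prevalence, group_params = group_params,
         correlation = correlation, spectrum_shift = spectrum_shift),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n) || length(spec$n) != 1 || is.na(spec$n) ||
      spec$n < 0 || spec$n != floor(spec$n)) {
    stop("invalid cohort_spec field 'n': must be a single non-negative integer",
         call. = FALSE)
  }
  p <- spec$prevalence
  if (!is.numeric(p) || length(p) != 4 ||
      !setequal(names(p), fibrosis_states())) {
    stop("invalid cohort_spec field 'prevalence': must be named over the four fibrosis states",
         call. = FALSE)
  }
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12) {
    stop("invalid cohort_spec field 'prevalence': entries must lie in [0,1] and sum to 1",
         call. = FALSE)
  }
  if (!is.numeric(spec$masld_prevalence) || spec$masld_prevalence < 0 ||
      spec$masld_prevalence > 1) {
    stop("invalid cohort_spec field 'masld_prevalence': must lie in [0,1]",
         call. = FALSE)
  }
  if (!is.numeric(spec$spectrum_shift) || spec$spectrum_shift < 0) {
    stop("invalid cohort_spec field 'spectrum_shift': must be >= 0",
         call. = FALSE)
  }
  for (st in fibrosis_states()) {
    for (v in cohort_biomarkers()) {
      g <- spec$group_params[[st]][[v]]
      if (is.null(g) || !is.finite(g$location) || !is.finite(g$scale) ||
          g$scale <= 0) {
        stop(sprintf("invalid cohort_spec field 'group_params': %s/%s missing or non-positive scale",
                     st, v), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Enrich a cohort specification towards a referral-population spectrum
#'
#' Secondary/tertiary-care cohorts carry a higher prevalence and severity of
#' fibrosis than the primary-care population a score was derived in (the
#' spectrum effect). This returns a new spec in which the odds of the
#' fibrotic states are multiplied by `1 + factor` (relative proportions of
#' significant/advanced/cirrhosis preserved), AST locations are raised, and
#' the stored `spectrum_shift` factor additionally skews LSM upwards within
#' each state's range at generation time. `factor = 0` is the identity.
#'
#' @param spec A [cohort_spec()].
#' @param factor Non-negative enrichment factor.
#' @return A new `cohort_spec`.
#' @export
spectrum_shift <- function(spec, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 0) {
    stop("invalid spectrum shift 'factor': must be a single non-negative number",
         call. = FALSE)
  }
  if (factor == 0) return(spec)
  out <- spec
  out$prevalence <- shift_prevalence(spec$prevalence, factor)
  for (st in setdiff(fibrosis_states(), "none_or_mild")) {
    out$group_params[[st]]$ast$location <-
      spec$group_params[[st]]$ast$location * (1 + 0.1 * factor)
  }
  # referral case-mix compression: the non-fibrotic group's AST drifts
  # towards the fibrotic range, eroding blood-marker discrimination
  w <- 1 - 1 / (1 + 0.3 * factor)
  loc_none <- spec$group_params$none_or_mild$ast$location
  loc_sig <- out$group_params$significant$ast$location
  out$group_params$none_or_mild$ast$location <-
    loc_none + w * (loc_sig - loc_none)
  out$spectrum_shift <- spec$spectrum_shift + factor
  validate_cohort_spec(out)
  out
}

# Multiply the odds of the fibrotic mass by (1 + factor), keeping relative
# proportions within the fibrotic states.
shift_prevalence <- function(prevalence, factor) {
  fib <- setdiff(fibrosis_states(), "none_or_mild")
  pf <- sum(prevalence[fib])
  if (pf == 0) return(prevalence)
  w <- pf * (1 + factor)
  new_pf <- w / (w + (1 - pf))
  out <- prevalence
  out[fib] <- prevalence[fib] / pf * new_pf
  out["none_or_mild"] <- 1 - new_pf
  out / sum(out)
}

#' Solve the spectrum-shift factor hitting a target fibrosis prevalence
#'
#' Bisection on the enrichment factor so that the shifted spec's probability
#' of LSM >= 8.1 kPa equals `target` (e.g. 105/218 for a referral cohort).
#'
#' @param spec A [cohort_spec()].
#' @param target Target P(LSM >= 8.1) in (current prevalence, 1).
#' @param tol Bisection tolerance on the prevalence.
#' @return The factor; `spectrum_shift(spec, factor)` attains the target.
#' @export
solve_spectrum_factor <- function(spec, target, tol = 1e-10) {
  fib <- setdiff(fibrosis_states(), "none_or_mild")
  p0 <- sum(spec$prevalence[fib])
  if (target <= p0 || target >= 1) {
    stop("target prevalence must exceed the spec's current fibrotic prevalence and be < 1",
         call. = FALSE)
  }
  f_at <- function(f) sum(shift_prevalence(spec$prevalence, f)[fib])
  lo <- 0
  hi <- 1
  while (f_at(hi) < target) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
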