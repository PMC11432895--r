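# Quantile function of a truncated distribution: map u in (0,1) onto the
# parent CDF restricted to [lo, hi].
q_truncated <- function(u, pfun, qfun, lo, hi, ...) {
  p_lo <- pfun(lo, ...)
  p_hi <- pfun(hi, ...)
  qfun(p_lo + u * (p_hi - p_lo), ...)
}

# Draw one biomarker for a block of subjects sharing a fibrosis state.
# u are copula uniforms; params as in default_group_params().
draw_marginal <- function(u, params) {
  lo <- params$range[1]
  hi <- params$range[2]
  if (params$dist == "tnorm") {
    q_truncated(u, stats::pnorm, stats::qnorm, lo, hi,
                mean = params$location, sd = params$scale)
  } else if (params$dist == "lnorm") {
    q_truncated(u, stats::plnorm, stats::qlnorm, lo, hi,
                meanlog = log(params$location), sdlog = params$scale)
  } else {
    stop("unknown marginal distribution: ", params$dist, call. = FALSE)
  }
}

#' Generate a synthetic diabetic cohort
#'
#' Draws `spec$n` subjects. Fibrosis states are sampled from the spec's
#' prevalences; biomarkers are drawn from a Gaussian copula (latent
#' correlation `spec$correlation`) with per-state marginals, so that rank
#' dependence between biomarkers is preserved while group-conditional medians
#' match the configured locations. LSM is drawn from disjoint per-state
#' ranges, so the stiffness thresholds (8.1, 12.1 kPa) and the state label
#' can never disagree. All subjects are diabetic by design (study inclusion
#' criterion). Identical specs (including seed) produce identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per subject and columns
#'   `id, age, sex, bmi, waist, ast, alt, platelets, albumin, elf, lsm,
#'   fibrosis_state, has_masld`. Albumin is in g/L; ELF in ELF units.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  vars <- cohort_biomarkers()
  states <- fibrosis_states()
  n <- spec$n
  cols <- c("id", "age", "sex", "bmi", "waist", "ast", "alt", "platelets",
            "albumin", "elf", "lsm", "fibrosis_state", "has_masld")
  if (n == 0) {
    out <- data.frame(id = character(), age = numeric(), sex = character(),
                      bmi = numeric(), waist = numeric(), ast = numeric(),
                      alt = numeric(), platelets = numeric(),
                      albumin = numeric(), elf = numeric(), lsm = numeric(),
                      fibrosis_state = character(), has_masld = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  withr::with_seed(spec$seed, {
    state <- sample(states, n, replace = TRUE, prob = spec$prevalence[states])
    sex <- sample(c("male", "female"), n, replace = TRUE)
    L <- chol(spec$correlation)
    Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
    U <- stats::pnorm(Z)
    colnames(U) <- vars
    # spectrum shift skews stiffness upwards within each state's range
    if (spec$spectrum_shift > 0) {
      U[, "lsm"] <- U[, "lsm"]^(1 / (1 + 0.5 * spec$spectrum_shift))
    }
    X <- matrix(NA_real_, nrow = n, ncol = length(vars),
                dimnames = list(NULL, vars))
    for (st in states) {
      idx <- which(state == st)
      if (!length(idx)) next
      for (v in vars) {
        X[idx, v] <- draw_marginal(U[idx, v], spec$group_params[[st]][[v]])
      }
    }
    fibrotic <- state != "none_or_mild"
    has_masld <- fibrotic |
      (stats::runif(n) < spec$masld_prevalence)
    data.frame(
      id = sprintf("S%05d", seq_len(n)),
      age = X[, "age"], sex = sex, bmi = X[, "bmi"], waist = X[, "waist"],
      ast = X[, "ast"], alt = X[, "alt"], platelets = X[, "platelets"],
      albumin = X[, "albumin"], elf = X[, "elf"], lsm = X[, "lsm"],
      fibrosis_state = state, has_masld = has_masld,
      stringsAsFactors = FALSE
    )
  })
}

cohort_columns <- function() {
  c("id", "age", "sex", "bmi", "waist", "ast", "alt", "platelets",
    "albumin", "elf", "lsm", "fibrosis_state", "has_masld")
}

#' Write a cohort to CSV
#'
#' Plain UTF-8 CSV with header
#' `id,age,sex,bmi,waist,ast,alt,platelets,albumin,elf,lsm,fibrosis_state,has_masld`
#' and "." as decimal separator.
#'
#' @param cohort Data.frame as returned by [generate_cohort()].
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(cohort[, cohort_columns()], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV, validating schema and invariants
#'
#' Rejects files with missing or extra columns, non-numeric labs, non-positive
#' lab values, or stiffness/state labels that disagree, reporting the first
#' offending data row number.
#'
#' @param path CSV written by [write_cohort()] (or hand-built to its schema).
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  expected <- cohort_columns()
  if (!identical(names(df), expected)) {
    stop("cohort file column mismatch: expected header ",
         paste(expected, collapse = ","), "; found ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  num_cols <- c("age", "bmi", "waist", "ast", "alt", "platelets",
                "albumin", "elf", "lsm")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("cohort parse error: non-numeric '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
    }
    neg <- which(vals <= 0)
    if (length(neg)) {
      stop(sprintf("cohort parse error: non-positive '%s' at data row %d",
                   col, neg[1]), call. = FALSE)
    }
    df[[col]] <- vals
  }
  bad_state <- which(!df$fibrosis_state %in% fibrosis_states())
  if (length(bad_state)) {
    stop(sprintf("cohort parse error: unknown fibrosis_state at data row %d",
                 bad_state[1]), call. = FALSE)
  }
  fibrotic <- df$fibrosis_state != "none_or_mild"
  mismatch <- which((df$lsm >= 8.1) != fibrotic)
  if (length(mismatch)) {
    stop(sprintf("cohort parse error: lsm/fibrosis_state mismatch at data row %d",
                 mismatch[1]), call. = FALSE)
  }
  df$has_masld <- df$has_masld %in% c("TRUE", "true", "1")
  df
}
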