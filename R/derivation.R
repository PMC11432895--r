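#' Split a cohort into derivation and validation subsets (2:1)
#'
#' Seeded random permutation; the derivation subset takes round(2n/3)
#' subjects, the validation subset the rest. Subsets are disjoint and
#' exhaustive.
#'
#' @param cohort Cohort data.frame with at least 3 rows.
#' @param seed Integer seed making the split reproducible.
#' @return List with elements `derivation` and `validation`.
#' @export
split_cohort <- function(cohort, seed) {
  n <- nrow(cohort)
  if (n < 3) stop("cohort too small to split (need >= 3 subjects)", call. = FALSE)
  n_der <- round(2 * n / 3)
  idx <- withr::with_seed(seed, sample.int(n))
  list(derivation = cohort[sort(idx[seq_len(n_der)]), , drop = FALSE],
       validation = cohort[sort(idx[-seq_len(n_der)]), , drop = FALSE])
}

#' Univariate screen of candidate predictors
#'
#' Continuous variables are compared between outcome groups with the
#' Mann-Whitney U test (tie-corrected normal approximation, two-sided);
#' categorical variables with Pearson's chi-square (no continuity
#' correction).
#'
#' @param cohort Cohort data.frame.
#' @param outcome Logical vector, one per record; both groups must be
#'   non-empty.
#' @param variables Character vector of column names to screen.
#' @return Data.frame with columns `variable, test, statistic, p_value`.
#'   For Mann-Whitney rows the statistic is U for the outcome-positive group.
#' @export
univariate_screen <- function(cohort, outcome, variables) {
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      ht <- stats::wilcox.test(x[outcome], x[!outcome],
                               exact = FALSE, correct = FALSE)
      data.frame(variable = v, test = "mann_whitney",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 stringsAsFactors = FALSE)
    } else {
      ht <- suppressWarnings(stats::chisq.test(table(x, outcome),
                                               correct = FALSE))
      data.frame(variable = v, test = "chi_square",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximises the Bernoulli log-likelihood by iteratively reweighted least
#' squares. Convergence is declared when the score vector (gradient of the
#' log-likelihood) has max-norm below `tol`, up to `max_iter` iterations.
#' Perfect separation is reported as non-convergence with a warning; the
#' last iterate's coefficients are still returned.
#'
#' @param data Data.frame of predictors and outcome.
#' @param predictors Character vector of predictor column names; none may be
#'   constant.
#' @param outcome Name of a logical/0-1 outcome column, or a vector.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Iteration cap.
#' @return Object of class `logistic_fit`: `coefficients` (named, intercept
#'   first), `log_likelihood`, `converged`, `n_iterations`, `fitted`
#'   (probabilities).
#' @export
fit_logistic <- function(data, predictors, outcome,
                         tol = 1e-8, max_iter = 100) {
  y <- if (is.character(outcome) && length(outcome) == 1) {
    data[[outcome]]
  } else {
    outcome
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  if (any(apply(X[, -1, drop = FALSE], 2, stats::sd) == 0)) {
    stop("constant predictor supplied", call. = FALSE)
  }
  beta <- numeric(ncol(X))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (converged) {
    # re-check after final update
    converged <- max(abs(drop(crossprod(X, y - mu)))) < tol
  }
  # perfect separation drives the deviance to zero with unbounded
  # coefficients; the score norm can still fall below tolerance there
  if (converged &&
      all(abs(y - mu) < 1e-6)) {
    converged <- FALSE
  }
  if (!converged) {
    warning("logistic fit did not converge (possible perfect separation); ",
            "returning last iterate", call. = FALSE)
  }
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, log_likelihood = ll,
                 converged = converged, n_iterations = iter, fitted = mu),
            class = "logistic_fit")
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and 0/1 outcomes.
#'
#' @param probabilities Numeric in [0, 1].
#' @param outcomes Logical/0-1 of the same length.
#' @return Score in [0, 1]; 0 is perfect.
#' @export
brier_score <- function(probabilities, outcomes) {
  if (length(probabilities) == 0) stop("empty input", call. = FALSE)
  if (length(probabilities) != length(outcomes)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  mean((probabilities - as.numeric(outcomes))^2)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are binned into (by default) deciles of predicted risk using
#' value quantiles, so the binning is invariant to record order; bins whose
#' quantile breaks coincide (heavy ties) are merged, as are bins with zero
#' expected events. The statistic is sum over bins of
#' (O - E)^2 / (E (1 - E/n_g)), referred to chi-square with (bins - 2)
#' degrees of freedom.
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param outcomes Logical/0-1 outcomes; both classes must be present.
#' @param groups Target number of risk bins (default 10).
#' @return List `statistic`, `p_value`, `df`, `table` (per-bin n, observed,
#'   expected).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 10) {
  y <- as.numeric(outcomes)
  p <- probabilities
  if (length(p) < groups) stop("need at least as many records as groups",
                               call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome must contain both classes",
                                  call. = FALSE)
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                   names = FALSE))
  if (length(breaks) < 3) stop("predicted probabilities too degenerate to bin",
                               call. = FALSE)
  bin <- cut(p, breaks = breaks, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(tapply(y, bin, length)),
    observed = as.vector(tapply(y, bin, sum)),
    expected = as.vector(tapply(p, bin, sum))
  )
  tab <- tab[!is.na(tab$n), , drop = FALSE]
  # merge bins with zero expected events into their upper neighbour
  i <- 1
  while (i <= nrow(tab)) {
    if (tab$expected[i] <= 0 || tab$expected[i] >= tab$n[i]) {
      j <- if (i < nrow(tab)) i + 1 else i - 1
      if (j < 1) break
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab <- tab[-i, , drop = FALSE]
      message("hosmer_lemeshow: merged a degenerate risk bin")
    } else {
      i <- i + 1
    }
  }
  g <- nrow(tab)
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- max(g - 2, 1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df, table = tab)
}

#' Simulate subjects from a planted logistic score model
#'
#' Draws BMI and AST from plausible diabetic-population marginals and the
#' outcome from a Bernoulli whose log-odds are the linear score with the
#' given coefficients. Used for parameter-recovery checks: fitting a
#' logistic model to this data should recover the planted coefficients.
#'
#' @param n Number of subjects.
#' @param coefficients List with `intercept`, `beta_bmi`, `beta_ast`
#'   (default: the published score's values).
#' @param seed Integer seed.
#' @return Data.frame with columns `bmi`, `ast`, `outcome`.
#' @export
simulate_planted_logistic <- function(n, coefficients = bimast_coefficients(),
                                      seed = 1) {
  withr::with_seed(seed, {
    bmi <- q_truncated(stats::runif(n), stats::pnorm, stats::qnorm,
                       17, 60, mean = 33, sd = 6)
    ast <- stats::qlnorm(stats::runif(n), meanlog = log(30), sdlog = 0.45)
    p <- stats::plogis(coefficients$intercept + coefficients$beta_bmi * bmi +
                         coefficients$beta_ast * ast)
    data.frame(bmi = bmi, ast = ast, outcome = stats::runif(n) < p)
  })
}
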