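test_that("2:1 split gives round(2n/3), disjoint, exhaustive, reproducible", {
  co <- tiny_cohort(287, seed = 31)
  sp <- split_cohort(co, seed = 1)
  expect_equal(nrow(sp$derivation), 191)
  expect_equal(nrow(sp$validation), 96)
  expect_length(intersect(sp$derivation$id, sp$validation$id), 0)
  expect_setequal(c(sp$derivation$id, sp$validation$id), co$id)
  expect_identical(split_cohort(co, seed = 1), sp)
  expect_false(identical(split_cohort(co, seed = 2)$derivation$id,
                         sp$derivation$id))
  tiny <- tiny_cohort(3, seed = 32)
  sp3 <- split_cohort(tiny, seed = 1)
  expect_equal(c(nrow(sp3$derivation), nrow(sp3$validation)), c(2, 1))
  expect_error(split_cohort(tiny[1:2, ], seed = 1), "too small")
})

test_that("Mann-Whitney U equals brute-force pair counting; extremes are extreme", {
  withr::with_seed(33, {
    for (i in 1:20) {
      a <- sample(round(runif(8, 0, 20)))  # with ties
      b <- sample(round(runif(11, 0, 20)))
      co <- data.frame(x = c(a, b))
      out <- c(rep(TRUE, 8), rep(FALSE, 11))
      res <- univariate_screen(co, out, "x")
      expect_equal(res$statistic, u_brute_force(a, b))
    }
  })
  # all of group A above group B: U = n_A * n_B and a tiny p-value
  co <- data.frame(x = c(101:110, 1:15))
  out <- rep(c(TRUE, FALSE), c(10, 15))
  res <- univariate_screen(co, out, "x")
  expect_equal(res$statistic, 10 * 15)
  expect_lt(res$p_value, 1e-4)
  expect_error(univariate_screen(co, rep(TRUE, 25), "x"), "both classes")
})

test_that("univariate screen holds its type-I error under the null", {
  withr::with_seed(34, {
    rejections <- replicate(400, {
      co <- data.frame(x = rnorm(100))
      out <- rep(c(TRUE, FALSE), 50)
      univariate_screen(co, out, "x")$p_value < 0.05
    })
  })
  rate <- mean(rejections)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("chi-square branch runs on categorical variables", {
  co <- data.frame(g = rep(c("a", "b"), each = 50),
                   stringsAsFactors = FALSE)
  out <- c(rep(TRUE, 40), rep(FALSE, 60))
  res <- univariate_screen(co, out, "g")
  expect_equal(res$test, "chi_square")
  expect_lt(res$p_value, 0.05)
})

test_that("IRLS logistic fit agrees with glm and respects the likelihood", {
  d <- simulate_planted_logistic(2000, seed = 35)
  fit <- fit_logistic(d, c("bmi", "ast"), "outcome")
  ref <- stats::glm(outcome ~ bmi + ast, data = d, family = stats::binomial())
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
  # fitted model is at least as likely as the null model
  null_ll <- {
    p0 <- mean(d$outcome)
    sum(d$outcome * log(p0) + (1 - d$outcome) * log(1 - p0))
  }
  expect_gte(fit$log_likelihood, null_ll)
})

test_that("null-model fit: slope near zero, intercept near logit prevalence", {
  withr::with_seed(36, {
    d <- data.frame(x = rnorm(20000), y = runif(20000) < 0.3)
  })
  fit <- fit_logistic(d, "x", "y")
  expect_lt(abs(fit$coefficients[["x"]]), 0.05)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - qlogis(0.3)), 0.08)
})

test_that("planted-coefficient recovery bias shrinks with sample size", {
  bias_at <- function(n) {
    fit <- fit_logistic(simulate_planted_logistic(n, seed = 37),
                        c("bmi", "ast"), "outcome")
    abs(fit$coefficients[["bmi"]] - 0.17)
  }
  b <- vapply(c(500, 5000, 50000), bias_at, numeric(1))
  expect_lt(b[3], b[1])
  expect_lt(b[3], 0.17 * 0.10)
})

test_that("perfect separation is flagged as non-convergence but returns coefficients", {
  d <- data.frame(x = c(-(5:1), 1:5), y = rep(c(FALSE, TRUE), each = 5))
  expect_warning(fit <- fit_logistic(d, "x", "y"), "converge")
  expect_false(fit$converged)
  expect_true(is.finite(fit$coefficients[["x"]]))
  expect_error(fit_logistic(data.frame(x = rep(1, 10), y = rep(c(TRUE, FALSE), 5)),
                            "x", "y"), "constant")
  expect_error(fit_logistic(data.frame(x = rnorm(10), y = rep(TRUE, 10)),
                            "x", "y"), "both classes")
})

test_that("Brier score: worked 3-record case and closed forms", {
  expect_equal(brier_score(c(0.2, 0.7, 0.9), c(0, 1, 1)), 0.14 / 3,
               tolerance = 1e-12)
  expect_equal(brier_score(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(brier_score(rep(0.5, 20), rep(c(0, 1), 10)), 0.25)
  expect_error(brier_score(numeric(0), numeric(0)), "empty")
  expect_error(brier_score(c(0.2, 1.4), c(0, 1)), "\\[0,1\\]")
})

test_that("Hosmer-Lemeshow: zero statistic under exact calibration, order-invariant,
           matches a brute-force bin accumulation", {
  # every bin's observed frequency equals its mean prediction exactly
  p <- rep(c(0.2, 0.4, 0.6, 0.8), each = 10)
  y <- unlist(lapply(c(0.2, 0.4, 0.6, 0.8), function(q) {
    rep(c(1, 0), c(q * 10, 10 - q * 10))
  }))
  hl <- hosmer_lemeshow(p, y, groups = 4)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1, tolerance = 1e-12)

  withr::with_seed(38, {
    p2 <- runif(200)
    y2 <- as.numeric(runif(200) < p2)
  })
  hl2 <- hosmer_lemeshow(p2, y2)
  perm <- withr::with_seed(39, sample(200))
  expect_equal(hosmer_lemeshow(p2[perm], y2[perm])$statistic, hl2$statistic,
               tolerance = 1e-12)
  # independent bin-sum oracle on the same quantile bins
  breaks <- unique(quantile(p2, probs = seq(0, 1, 0.1), names = FALSE))
  bin <- cut(p2, breaks, include.lowest = TRUE)
  stat_oracle <- 0
  for (b in levels(bin)) {
    idx <- bin == b
    O <- sum(y2[idx]); E <- sum(p2[idx]); ng <- sum(idx)
    stat_oracle <- stat_oracle + (O - E)^2 / (E * (1 - E / ng))
  }
  expect_equal(hl2$statistic, stat_oracle, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow accepts a well-calibrated model most of the time", {
  withr::with_seed(40, {
    keep <- replicate(200, {
      x <- rnorm(1000)
      y <- runif(1000) < plogis(-1 + x)
      fit <- fit_logistic(data.frame(x = x), "x", y)
      hosmer_lemeshow(fit$fitted, y)$p_value > 0.05
    })
  })
  expect_gte(mean(keep), 0.90)
})
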