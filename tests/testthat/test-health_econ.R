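test_that("packaged placeholder config loads and validates", {
  cfg <- default_econ_config()
  expect_s3_class(cfg, "econ_config")
  P <- build_transition_matrix(cfg)
  expect_equal(unname(rowSums(P)), rep(1, 9), tolerance = 1e-12)
  expect_equal(P["DEAD", "DEAD"], 1)
  bad <- cfg
  bad$transitions$DC$DEAD <- 1.4
  expect_error(validate_econ_config(bad), "out of \\[0,1\\]")
  bad2 <- cfg
  bad2$utilities$DC <- 1.2
  expect_error(validate_econ_config(bad2), "utility")
  bad3 <- cfg
  bad3$transitions$SLD_fn$CC_fn <- 0.001  # slower than diagnosed arm
  expect_error(validate_econ_config(bad3), "undiagnosed")
})

test_that("decision tree splits prevalence by test accuracy and conserves mass", {
  # printed US+LFTs proxy: sens 0.35, spec 0.65 on 17% disease prevalence
  tree <- build_decision_tree(c(MLD = 0.83, SLD = 0.14, CC = 0.03),
                              sens = 0.35, spec = 0.65,
                              test_cost = 10, referral_cost = 100)
  expect_equal(unname(tree$initial["SLD_fn"] + tree$initial["CC_fn"]),
               0.17 * 0.65, tolerance = 1e-12)
  expect_equal(sum(tree$initial), 1, tolerance = 1e-12)
  expect_equal(tree$upfront_cost_pp,
               10 + 100 * (0.35 * 0.17 + 0.35 * 0.83), tolerance = 1e-12)
  # perfect test: no false-negative mass, no false-positive referrals
  perf <- build_decision_tree(c(MLD = 0.8, SLD = 0.15, CC = 0.05), 1, 1,
                              test_cost = 0, referral_cost = 100)
  expect_equal(unname(perf$initial["SLD_fn"] + perf$initial["CC_fn"]), 0)
  expect_equal(perf$upfront_cost_pp, 100 * 0.2)
  expect_equal(perf$correct_diagnosis_rate, 1)
  withr::with_seed(51, {
    for (i in 1:20) {
      pv <- runif(3); pv <- pv / sum(pv)
      tr <- build_decision_tree(c(MLD = pv[1], SLD = pv[2], CC = pv[3]),
                                runif(1), runif(1))
      expect_equal(sum(tr$initial), 1, tolerance = 1e-12)
    }
  })
  expect_error(build_decision_tree(c(MLD = 0.5, SLD = 0.4, CC = 0.3), 1, 1),
               "prevalence")
  expect_error(build_decision_tree(c(MLD = 0.8, SLD = 0.15, CC = 0.05), 1.2, 1),
               "\\[0,1\\]")
})

test_that("Markov chain: identity chain, geometric closed form, linearity", {
  cfg <- default_econ_config()
  # single alive state, utility 1, no discounting, 5 years -> 5 QALYs/person
  cfg5 <- cfg
  cfg5$horizon <- 5
  cfg5$discount_rate <- 0
  for (st in setdiff(econ_states(), "DEAD")) cfg5$transitions[[st]] <- list()
  for (st in econ_states()) {
    cfg5$utilities[[st]] <- 1
    cfg5$costs[[st]] <- 0
  }
  cfg5$utilities$DEAD <- 0
  init <- setNames(c(1, rep(0, 8)), econ_states())
  out5 <- run_markov(init, cfg5)
  expect_equal(out5$qalys_pp, 5, tolerance = 1e-12)

  # two-state alive -> dead at 0.2/yr, 3.5% discounting: geometric series
  cfgg <- cfg5
  cfgg$discount_rate <- 0.035
  cfgg$horizon <- 2000
  cfgg$transitions$MLD <- list(DEAD = 0.2)
  outg <- run_markov(init, cfgg)
  expect_equal(outg$life_years_pp, 1 / (1 - 0.8 / 1.035), tolerance = 1e-10)

  # cohort totals scale exactly linearly in cohort size
  cfg2 <- cfg
  cfg2$cohort_size <- cfg$cohort_size * 2
  tree <- build_decision_tree(cfg$entry_prevalence, 0.9, 0.8, 5, 250)
  a <- run_markov(tree$initial, cfg, tree$upfront_cost_pp)
  b <- run_markov(tree$initial, cfg2, tree$upfront_cost_pp)
  expect_equal(b$qalys_cohort, 2 * a$qalys_cohort, tolerance = 1e-12)
  expect_equal(b$cost_cohort, 2 * a$cost_cohort, tolerance = 1e-12)
})

test_that("occupancy is conserved every cycle and death is monotone", {
  withr::with_seed(52, {
    for (i in 1:40) {
      cfg <- random_econ_config()
      tree <- build_decision_tree(cfg$entry_prevalence, runif(1), runif(1))
      out <- run_markov(tree$initial, cfg)
      expect_lt(max(abs(rowSums(out$trace) - 1)), 1e-10)
      expect_true(all(diff(out$trace[, "DEAD"]) >= -1e-12))
    }
  })
  bad <- default_econ_config()
  bad$transitions$MLD$DEAD <- -0.1
  init <- setNames(c(1, rep(0, 8)), econ_states())
  expect_error(run_markov(init, bad), "stochastic")
})

test_that("discounting: rate 0 reproduces undiscounted sums; positive rate matches
           a per-cycle product oracle and never exceeds undiscounted totals", {
  cfg <- default_econ_config()
  tree <- build_decision_tree(cfg$entry_prevalence, 0.7, 0.6, 5, 250)
  out <- run_markov(tree$initial, cfg, tree$upfront_cost_pp)
  oracle <- discounted_totals_oracle(out$trace, cfg)
  expect_equal(out$life_years_pp, oracle$life_years, tolerance = 1e-10)
  expect_equal(out$qalys_pp, oracle$qalys, tolerance = 1e-10)
  expect_equal(out$cost_pp - tree$upfront_cost_pp, oracle$cost,
               tolerance = 1e-10)

  cfg0 <- cfg
  cfg0$discount_rate <- 0
  out0 <- run_markov(tree$initial, cfg0)
  undisc <- sum(out0$trace[seq_len(cfg$horizon), econ_states() != "DEAD"])
  expect_equal(out0$life_years_pp, undisc, tolerance = 1e-12)
  expect_lt(out$life_years_pp, out0$life_years_pp)
  expect_lt(out$qalys_pp, out0$qalys_pp)
})

test_that("diagnosed arm lives at least as long as the undiagnosed arm", {
  withr::with_seed(53, {
    for (i in 1:15) {
      cfg <- random_econ_config()
      # enforce the fn >= dx ordering the model assumes
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
      dx <- setNames(c(0, 1, rep(0, 7)), econ_states())
      fn <- setNames(c(0, 0, 1, rep(0, 6)), econ_states())
      expect_gte(run_markov(dx, cfg)$life_years_pp,
                 run_markov(fn, cfg)$life_years_pp - 1e-12)
    }
  })
})

test_that("ICER arithmetic, dominance flags, and self-comparison", {
  mk <- function(cost, qaly) list(cost_pp = cost, qalys_pp = qaly)
  expect_equal(icer(mk(100, 2.5), mk(100, 2))$icer, 0)
  expect_equal(icer(mk(1100, 2.5), mk(100, 2))$icer, 2000)
  expect_equal(icer(mk(50, 2.5), mk(100, 2))$status, "dominant")
  expect_equal(icer(mk(500, 1.5), mk(100, 2))$status, "dominated")
  expect_equal(icer(mk(500, 2), mk(100, 2))$status, "undefined")
  soc <- mk(100, 2)
  expect_equal(icer(soc, soc)$status, "undefined")
})

test_that("a strictly better test at equal cost never yields fewer QALYs", {
  withr::with_seed(54, {
    for (i in 1:15) {
      cfg <- random_econ_config()
      s1 <- runif(1, 0.1, 0.8); sp1 <- runif(1, 0.1, 0.8)
      s2 <- s1 + runif(1, 0, 1 - s1)
      sp2 <- sp1 + runif(1, 0, 1 - sp1)
      acc <- data.frame(name = c("worse", "better", "SOC"),
                        sensitivity = c(s1, s2, 0.1),
                        specificity = c(sp1, sp2, 0.9),
                        test_cost = c(10, 10, 1))
      res <- run_cea(cfg, acc)
      expect_gte(res$qalys_cohort[res$strategy == "better"],
                 res$qalys_cohort[res$strategy == "worse"] - 1e-9)
    }
  })
})

test_that("one-way sensitivity: degenerate range, bound checks, cost homogeneity", {
  cfg <- default_econ_config()
  co <- tiny_cohort(2000, seed = 55)
  acc <- strategy_accuracy(co)
  ow <- one_way_sensitivity(cfg, acc, "costs.DC", c(11500, 11500))
  expect_equal(ow$icer[1], ow$icer[2])
  expect_error(one_way_sensitivity(cfg, acc, "transitions.SLD_fn.CC_fn",
                                   c(0.5, 1.5)), "\\[0,1\\]")
  expect_error(one_way_sensitivity(cfg, acc, "nonexistent.path", 1),
               "unknown parameter")
  # scaling every cost by k scales the ICER by k
  base <- run_cea(cfg, acc)
  k <- 3
  cfgk <- cfg
  for (st in econ_states()) cfgk$costs[[st]] <- cfg$costs[[st]] * k
  cfgk$referral_cost <- cfg$referral_cost * k
  acck <- acc
  acck$test_cost <- acc$test_cost * k
  scaled <- run_cea(cfgk, acck)
  i <- match("BIMAST", base$strategy)
  expect_equal(scaled$icer_vs_soc[i], k * base$icer_vs_soc[i],
               tolerance = 1e-9)
})

test_that("shorter horizon raises every strategy's ICER", {
  cfg <- default_econ_config()
  acc <- strategy_accuracy(tiny_cohort(2000, seed = 56))
  for (nm in setdiff(acc$name, "SOC")) {
    ow <- one_way_sensitivity(cfg, acc, "horizon", c(5, 40), strategy = nm)
    expect_gt(ow$icer[ow$value == 5], ow$icer[ow$value == 40])
  }
})

test_that("PSA: seeded determinism, degenerate distributions reproduce base case,
           draw means track the distribution means", {
  cfg <- default_econ_config()
  cfg$horizon <- 20
  acc <- strategy_accuracy(tiny_cohort(1000, seed = 57))
  d1 <- psa(cfg, acc, n_draws = 8, seed = 5)
  d2 <- psa(cfg, acc, n_draws = 8, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1, psa(cfg, acc, n_draws = 8, seed = 6)))
  expect_error(psa(cfg, acc, n_draws = 0), "n_draws")

  degen <- cfg
  degen$psa$n_eff_probabilities <- Inf
  degen$psa$n_eff_utilities <- Inf
  degen$psa$cost_cv <- 0
  dd <- psa(degen, acc, n_draws = 3, seed = 1)
  base <- run_cea(cfg, acc)
  for (nm in acc$name) {
    expect_equal(unique(dd$cost_pp[dd$strategy == nm]),
                 base$lifetime_cost_pp[base$strategy == nm],
                 tolerance = 1e-10)
  }

  # law of large numbers on the parameter draws themselves
  withr::with_seed(58, {
    draws <- replicate(4000, bimast:::draw_psa_config(cfg)$utilities$DC)
  })
  m <- cfg$utilities$DC
  n_eff <- cfg$psa$n_eff_utilities
  se <- sqrt(m * (1 - m) / (n_eff + 1)) / sqrt(4000)
  expect_lt(abs(mean(draws) - m), 3 * se)
})

test_that("CEAC: cheapest wins at zero willingness-to-pay, highest-QALY wins at
           infinity, probabilities sum to one", {
  draws <- data.frame(
    draw = rep(1:3, each = 2),
    strategy = rep(c("A", "B"), 3),
    cost_pp = rep(c(100, 500), 3),
    qaly_pp = rep(c(1, 2), 3)
  )
  cc <- ceac(draws, c(0, 1e9))
  expect_equal(cc$probability[cc$threshold == 0 & cc$strategy == "A"], 1)
  expect_equal(cc$probability[cc$threshold == 1e9 & cc$strategy == "B"], 1)
  agg <- tapply(cc$probability, cc$threshold, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  expect_error(ceac(draws, numeric(0)), "empty")
})

test_that("CEAC Monte-Carlo acceptability matches the normal closed form", {
  n <- 4000
  withr::with_seed(59, {
    qa <- rnorm(n, 1.00, 0.10)
    qb <- rnorm(n, 1.05, 0.10)
  })
  draws <- data.frame(
    draw = rep(seq_len(n), each = 2),
    strategy = rep(c("A", "B"), n),
    cost_pp = rep(c(1000, 2000), n),
    qaly_pp = as.vector(rbind(qa, qb))
  )
  lambda <- 15000
  cc <- ceac(draws, lambda)
  # P(lambda qB - 2000 > lambda qA - 1000) under independent normals
  mu <- lambda * 0.05 - 1000
  sd_d <- lambda * 0.10 * sqrt(2)
  p_closed <- pnorm(mu / sd_d)
  p_mc <- cc$probability[cc$strategy == "B"]
  expect_lt(abs(p_mc - p_closed), 2 * sqrt(p_closed * (1 - p_closed) / n))
})
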