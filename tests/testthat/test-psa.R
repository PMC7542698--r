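test_that("psa config validates iteration count and threshold grid", {
  expect_error(psa_config(n_iterations = 0), "n_iterations")
  expect_error(psa_config(thresholds = c(5000, 1000)), "thresholds")
  expect_error(psa_config(thresholds = c(-1, 1000)), "thresholds")
})

test_that("moment-matched sampling distributions hit their means", {
  set.seed(88)
  g <- pcmarkov:::draw_cost(10000, 5000, 500, "gamma")
  expect_true(all(g > 0))
  expect_equal(mean(g), 5000, tolerance = 15 / 5000)
  expect_equal(sd(g), 500, tolerance = 0.05)
  b <- pcmarkov:::draw_utility(10000, 0.8, 0.05, "beta")
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(mean(b), 0.8, tolerance = 0.002 / 0.8)
  expect_equal(sd(b), 0.05, tolerance = 0.05)
  # zero SE is degenerate
  expect_identical(pcmarkov:::draw_cost(5, 100, 0, "gamma"), rep(100, 5))
  expect_identical(pcmarkov:::draw_utility(5, 0.7, 0, "beta"), rep(0.7, 5))
})

test_that("degenerate PSA reproduces the deterministic result exactly", {
  m <- quick_model(quick_transitions(0.08, 0.01, 0.2, 0.3),
                   const_life_table(0.03))
  det <- evaluate_model(m)
  expect_warning(draws <- run_psa(m, psa_config(n_iterations = 3, seed = 4)),
                 "degenerate|deterministic")
  for (strat in pc_strategies()) {
    d <- draws[draws$strategy == strat, ]
    expect_equal(d$cost, rep(det$cost[det$strategy == strat], 3),
                 tolerance = 1e-12)
    expect_equal(d$qaly, rep(det$qaly[det$strategy == strat], 3),
                 tolerance = 1e-12)
  }
  expect_warning(s1 <- sample_inputs(m, psa_config(n_iterations = 2, seed = 4), 1),
                 "deterministic")
  expect_equal(s1$state_values$utility, m$state_values$utility)
})

test_that("PSA draws replay exactly for a fixed seed and iteration", {
  cohort <- generate_cohort(test_config())
  tr <- fit_all_transitions(cohort)
  sv <- estimate_state_values(cohort)
  m <- decision_model(tr, default_life_table(), sv)
  cfg <- psa_config(n_iterations = 5, seed = 31)
  d1 <- run_psa(m, cfg)
  d2 <- run_psa(m, cfg)
  expect_identical(d1, d2)
  # single-iteration sampling is order-independent
  s3a <- sample_inputs(m, cfg, 3)
  junk <- sample_inputs(m, cfg, 1)
  s3b <- sample_inputs(m, cfg, 3)
  expect_equal(s3a$state_values$utility, s3b$state_values$utility)
  expect_equal(s3a$transitions$stable_progression$coefficients,
               s3b$transitions$stable_progression$coefficients)
  # different master seed changes the draws
  d3 <- run_psa(m, psa_config(n_iterations = 5, seed = 32))
  expect_false(identical(d1$cost, d3$cost))
})

test_that("percentile CI uses linear interpolation of order statistics", {
  ci <- percentile_ci(1:10000)
  expect_equal(unname(ci), c(250.975, 9750.025), tolerance = 1e-9)
  expect_identical(unname(percentile_ci(rep(7, 10))), c(7, 7))
  set.seed(12)
  x <- rnorm(20000)
  ci2 <- percentile_ci(x)
  expect_equal(unname(ci2[2] + ci2[1]), 0, tolerance = 0.05)
  expect_error(percentile_ci(1), "two draws")
})

test_that("percentile intervals widen with coverage", {
  cohort <- generate_cohort(test_config())
  cea <- evaluate_strategies(cohort, psa = psa_config(n_iterations = 200,
                                                      seed = 13))
  nmb <- with(subset(cea$draws, strategy == "AM"),
              net_monetary_benefit(qaly, cost))
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95), function(lv) {
    ci <- percentile_ci(nmb, lv)
    unname(ci[2] - ci[1])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("CEAC probabilities are winner fractions that sum to one", {
  # strategy B dominates every draw
  cost <- cbind(A = rep(100, 20), B = rep(50, 20))
  qaly <- cbind(A = rep(1, 20), B = rep(2, 20))
  cc <- ceac(manual_draws(cost, qaly), thresholds = c(0, 10000, 20000))
  expect_true(all(cc$probability[cc$strategy == "B"] == 1))
  expect_true(all(cc$probability[cc$strategy == "A"] == 0))
  # identical strategies split the tie equally
  cc2 <- ceac(manual_draws(cbind(A = rep(10, 5), B = rep(10, 5)),
                           cbind(A = rep(1, 5), B = rep(1, 5))),
              thresholds = c(0, 5000))
  expect_true(all(cc2$probability == 0.5))
  # at threshold 0 the cheapest strategy wins each draw
  set.seed(3)
  cost3 <- cbind(A = runif(50, 50, 150), B = runif(50, 50, 150))
  qaly3 <- cbind(A = runif(50, 1, 3), B = runif(50, 1, 3))
  cc3 <- ceac(manual_draws(cost3, qaly3), thresholds = 0)
  expect_equal(cc3$probability[cc3$strategy == "A"],
               mean(cost3[, "A"] < cost3[, "B"]))
})

test_that("CEAC probabilities sum to one on real PSA draws", {
  cohort <- generate_cohort(test_config())
  cea <- evaluate_strategies(cohort,
                             psa = psa_config(n_iterations = 100, seed = 14,
                                              thresholds = seq(0, 50000, 5000)))
  sums <- as.numeric(tapply(cea$ceac$probability, cea$ceac$threshold, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cea$ceac$probability >= 0 & cea$ceac$probability <= 1))
})
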