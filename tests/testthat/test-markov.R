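test_that("transition matrix applies mortality first, then disease hazards", {
  # all disease hazards zero: living rows are [stay 1-q, death_other q]
  m <- quick_model(life_table = const_life_table(0.1))
  tm <- build_matrix(m, "AM", 0)
  for (s in pc_living_states()) {
    expect_equal(unname(tm[s, s]), 0.9, tolerance = 1e-14)
    expect_equal(unname(tm[s, "death_other"]), 0.1, tolerance = 1e-14)
  }
  # q_other = 0, exponential 0.2 progression->metastasis
  m2 <- quick_model(quick_transitions(rate_pm = 0.2))
  tm2 <- build_matrix(m2, "RT", 3)
  expect_equal(unname(tm2["progression", "metastatic"]), 1 - exp(-0.2),
               tolerance = 1e-12)
  # no backward or forbidden edges
  expect_equal(unname(tm2["metastatic", "progression"]), 0)
  expect_equal(unname(tm2["stable", "death_pc"]), 0)
  expect_equal(unname(tm2["progression", "death_pc"]), 0)
  expect_equal(unname(tm2["death_pc", ]), c(0, 0, 0, 1, 0))
})

test_that("built matrices are row-stochastic on a randomised parameter grid", {
  set.seed(19)
  for (rep in 1:20) {
    tr <- quick_transitions(rate_sp = runif(1, 0, 0.5),
                            rate_sm = runif(1, 0, 0.5),
                            rate_pm = runif(1, 0, 1),
                            rate_md = runif(1, 0, 1))
    m <- quick_model(tr, const_life_table(runif(1, 0, 0.3)))
    tm <- build_matrix(m, "AM", sample(0:40, 1))
    expect_true(all(abs(rowSums(tm) - 1) < 1e-12))
    expect_true(all(tm >= 0))
  }
})

test_that("missing transitions are reported by edge name", {
  tr <- quick_transitions()
  tr$metastatic_death <- NULL
  expect_error(decision_model(tr, zero_life_table(), quick_state_values()),
               "metastatic_death")
})

test_that("cohort runs conserve occupancy and reproduce closed forms", {
  # no hazards at all: cohort stays 100% stable
  m0 <- quick_model()
  tr0 <- run_cohort(m0, "AM")
  expect_true(all(tr0$stable == 1))
  # mortality only, constant q = 0.1: stable occupancy is 0.9^t
  m1 <- quick_model(life_table = const_life_table(0.1))
  tr1 <- run_cohort(m1, "AM")
  expect_equal(tr1$stable, 0.9^(0:50), tolerance = 1e-12)
  expect_equal(tr1$death_other, 1 - 0.9^(0:50), tolerance = 1e-12)
  # conservation and death monotonicity on a random grid
  set.seed(23)
  for (rep in 1:10) {
    tr <- quick_transitions(runif(1, 0, 0.3), runif(1, 0, 0.3),
                            runif(1, 0, 0.8), runif(1, 0, 0.8))
    m <- quick_model(tr, const_life_table(runif(1, 0, 0.2)))
    trace <- run_cohort(m, "AM")
    occ <- as.matrix(as.data.frame(trace)[, pc_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
    dead <- occ[, "death_pc"] + occ[, "death_other"]
    expect_true(all(diff(dead) >= -1e-14))
  }
})

test_that("the trace matches step-by-step matrix multiplication", {
  m <- quick_model(quick_transitions(0.1, 0.02, 0.3, 0.4),
                   const_life_table(0.05))
  trace <- run_cohort(m, "RP")
  v <- c(1, 0, 0, 0, 0)
  for (t in 0:49) v <- as.vector(v %*% build_matrix(m, "RP", t))
  expect_equal(unname(as.matrix(as.data.frame(trace)[51, pc_states()])[1, ]),
               v, tolerance = 1e-12)
})

test_that("horizon must exceed the starting age", {
  expect_error(quick_model(horizon_age = 50), "horizon")
  expect_error(quick_model(horizon_age = 40), "horizon")
})

test_that("cycle outcomes weight occupancy by utility and cost", {
  sv <- quick_state_values()
  m <- quick_model(state_values = sv)
  trace <- run_cohort(m, "AM")  # 100% stable forever
  out <- cycle_outcomes(trace, sv, "AM", half_cycle = FALSE)
  expect_equal(out$qaly, rep(0.8, 50))
  expect_equal(out$cost, rep(550, 50))
  # half-cycle correction is a no-op when occupancy is constant
  out_h <- cycle_outcomes(trace, sv, "AM", half_cycle = TRUE)
  expect_equal(out_h$qaly, out$qaly)
  expect_error(cycle_outcomes(trace, sv, "XX"), "XX")
})

test_that("death entrants incur the terminal cost once", {
  # constant 10% other-cause mortality, no disease, no recurring costs
  sv <- state_values(utility = c(stable = 1, progression = 1, metastatic = 1),
                     cost = matrix(0, 3, 3,
                                   dimnames = list(pc_living_states(),
                                                   pc_strategies())),
                     terminal_cost = 3000)
  m <- quick_model(life_table = const_life_table(0.1), state_values = sv)
  trace <- run_cohort(m, "AM")
  out <- cycle_outcomes(trace, sv, "AM", half_cycle = FALSE)
  # 0.1 of the surviving cohort dies each cycle: cost = 3000 * 0.1 * 0.9^t
  expect_equal(out$cost, 3000 * 0.1 * 0.9^(0:49), tolerance = 1e-12)
  # total terminal spend over an infinite horizon would be 3000 per member
  expect_equal(sum(out$cost) / 3000, 1 - 0.9^50, tolerance = 1e-12)
  # all occupancy dead: QALY increment 0
  sv0 <- quick_state_values()
  m2 <- quick_model(life_table = const_life_table(1), state_values = sv0)
  trace2 <- run_cohort(m2, "AM")
  out2 <- cycle_outcomes(trace2, sv0, "AM", half_cycle = FALSE)
  expect_equal(out2$qaly[-1], rep(0, 49))
})

test_that("raising any disease hazard never increases total QALYs", {
  base <- c(sp = 0.05, sm = 0.01, pm = 0.2, md = 0.3)
  qaly_of <- function(h) {
    m <- quick_model(quick_transitions(h["sp"], h["sm"], h["pm"], h["md"]),
                     const_life_table(0.02))
    trace <- run_cohort(m, "AM")
    out <- cycle_outcomes(trace, m$state_values, "AM")
    lifetime_totals(out, 0.035)$qaly
  }
  q0 <- qaly_of(base)
  for (edge in names(base)) {
    for (bump in c(0.05, 0.2)) {
      h <- base
      h[edge] <- h[edge] + bump
      expect_lte(qaly_of(h), q0 + 1e-12)
    }
  }
})

test_that("trace CSV uses the documented occupancy columns", {
  m <- quick_model(quick_transitions(0.1, 0.02, 0.3, 0.4),
                   const_life_table(0.05))
  trace <- run_cohort(m, "RT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  df <- read.csv(path)
  expect_named(df, c("cycle", "age", "p_stable", "p_progression",
                     "p_metastatic", "p_death_pc", "p_death_other"))
  expect_equal(df$p_stable, trace$stable, tolerance = 1e-9)
})
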