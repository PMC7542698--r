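# Shared in-code fixtures for the suite.

# life table with zero mortality over the model ages
zero_life_table <- function(ages = 50:100) {
  life_table(ages, q_all = rep(0, length(ages)),
             deaths_all = rep(0, length(ages)),
             deaths_c61 = rep(0, length(ages)))
}

# constant all-cause mortality, no prostate-cancer deaths
const_life_table <- function(q, ages = 50:100) {
  life_table(ages, q_all = rep(q, length(ages)),
             deaths_all = rep(1000, length(ages)),
             deaths_c61 = rep(0, length(ages)))
}

# simple deterministic state values (no SEs)
quick_state_values <- function(u_stable = 0.8, u_prog = 0.75, u_met = 0.65,
                               terminal_cost = 3000) {
  state_values(
    utility = c(stable = u_stable, progression = u_prog, metastatic = u_met),
    cost = matrix(c(550, 450, 500,
                    1200, 1200, 1200,
                    5000, 5000, 5000),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(pc_living_states(), pc_strategies())),
    terminal_cost = terminal_cost)
}

# transition set with user-chosen constant hazards (exponential edges)
quick_transitions <- function(rate_sp = 0, rate_sm = 0, rate_pm = 0,
                              rate_md = 0) {
  list(
    stable_progression = transition_model("exponential", rate = rate_sp,
                                          transition = "stable_progression"),
    stable_metastasis = transition_model("exponential", rate = rate_sm,
                                         transition = "stable_metastasis"),
    progression_metastasis = transition_model("exponential", rate = rate_pm,
                                              transition = "progression_metastasis"),
    metastatic_death = transition_model("exponential", rate = rate_md,
                                        transition = "metastatic_death")
  )
}

quick_model <- function(transitions = quick_transitions(),
                        life_table = zero_life_table(),
                        state_values = quick_state_values(), ...) {
  decision_model(transitions, life_table, state_values, ...)
}

# hand-built PSA draws object for CEAC unit tests
manual_draws <- function(cost, qaly, strategies = colnames(cost)) {
  n <- nrow(cost)
  out <- do.call(rbind, lapply(seq_along(strategies), function(j) {
    data.frame(iteration = seq_len(n), strategy = strategies[j],
               cost = cost[, j], qaly = qaly[, j], stringsAsFactors = FALSE)
  }))
  attr(out, "strategies") <- strategies
  class(out) <- c("pc_psa_draws", "data.frame")
  out
}

# generator config scaled down for fast tests
test_config <- function(...) {
  generator_config(n_per_arm = 100, seed = 11, ...)
}
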