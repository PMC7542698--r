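# Five-state annual-cycle Markov cohort engine.  Within a cycle, other-cause
# death takes precedence: its probability is applied first to every living
# state and the disease transition probabilities are scaled by the remaining
# (1 - q_other).  Prostate-cancer death is reachable only from the
# metastatic state; both death states are absorbing.

#' Bundle fitted inputs into a runnable decision model
#'
#' @param transitions Named list of `pc_transition_model` objects with
#'   elements `stable_progression`, `stable_metastasis`,
#'   `progression_metastasis`, `metastatic_death`.  The stable-state exits
#'   may carry arm covariates; downstream transitions are shared.
#' @param life_table A [life_table()] covering `start_age:horizon_age`.
#' @param state_values A [state_values()] object.
#' @param start_age Cohort starting age (default 50).
#' @param horizon_age Model horizon; occupancy beyond is ignored
#'   (default 100).
#' @param discount_rate Annual discount rate for costs and QALYs
#'   (UK NICE reference case 3.5%).
#' @param half_cycle Apply the half-cycle correction (trapezoid averaging of
#'   start- and end-of-cycle occupancy, equivalent to the standard
#'   first/last half-cycle adjustment for time-constant payoffs)?
#' @param strategies Strategy labels to evaluate.
#' @return A `pc_decision_model`.
#' @export
decision_model <- function(transitions, life_table, state_values,
                           start_age = 50, horizon_age = 100,
                           discount_rate = 0.035, half_cycle = TRUE,
                           strategies = pc_strategies()) {
  missing_tr <- setdiff(pc_transitions(), names(transitions))
  if (length(missing_tr) > 0) {
    stop("missing transition model for edge(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  for (tr in pc_transitions()) {
    if (!inherits(transitions[[tr]], "pc_transition_model")) {
      stop(sprintf("transitions$%s is not a pc_transition_model", tr),
           call. = FALSE)
    }
  }
  stopifnot(inherits(life_table, "pc_life_table"),
            inherits(state_values, "pc_state_values"))
  if (horizon_age <= start_age) {
    stop("horizon_age must exceed start_age", call. = FALSE)
  }
  ages <- start_age:(horizon_age - 1)
  if (!all(ages %in% life_table$age)) {
    stop("life table does not cover the model ages", call. = FALSE)
  }
  structure(
    list(transitions = transitions, life_table = life_table,
         state_values = state_values, start_age = start_age,
         horizon_age = horizon_age, discount_rate = discount_rate,
         half_cycle = isTRUE(half_cycle), strategies = strategies),
    class = "pc_decision_model"
  )
}

#' @export
print.pc_decision_model <- function(x, ...) {
  cat(sprintf("<pc_decision_model> ages %d-%d, %d strategies (%s), discount %.1f%%, half-cycle %s\n",
              x$start_age, x$horizon_age, length(x$strategies),
              paste(x$strategies, collapse = ", "),
              100 * x$discount_rate, if (x$half_cycle) "on" else "off"))
  for (tr in pc_transitions()) {
    m <- x$transitions[[tr]]
    cat(sprintf("  %-24s %s\n", tr, m$family))
  }
  invisible(x)
}

# arm to feed into a transition model: only if it was fitted with arms
tr_arm <- function(model, strategy) {
  if (is.null(model$arm_levels)) NULL else strategy
}

#' Build the annual transition matrix for one strategy and cycle
#'
#' Rows and columns follow [pc_states()].  Other-cause mortality at the
#' cohort's current age is applied first to every living state; the disease
#' transition probabilities for the cycle are scaled by `1 - q_other`; the
#' remainder stays put.  Absorbing rows are identity.
#'
#' @param model A [decision_model()].
#' @param strategy Strategy label.
#' @param cycle Cycle index (0 = year from `start_age` to `start_age + 1`).
#' @return A 5x5 row-stochastic matrix.
#' @export
build_matrix <- function(model, strategy, cycle) {
  stopifnot(inherits(model, "pc_decision_model"), cycle >= 0)
  states <- pc_states()
  age <- model$start_age + cycle
  q_o <- other_cause_probability(model$life_table, age)
  tr <- model$transitions
  p_sp <- annual_transition_probability(tr$stable_progression, cycle,
                                        arm = tr_arm(tr$stable_progression, strategy))
  p_sm <- annual_transition_probability(tr$stable_metastasis, cycle,
                                        arm = tr_arm(tr$stable_metastasis, strategy))
  p_pm <- annual_transition_probability(tr$progression_metastasis, cycle,
                                        arm = tr_arm(tr$progression_metastasis, strategy))
  p_md <- annual_transition_probability(tr$metastatic_death, cycle,
                                        arm = tr_arm(tr$metastatic_death, strategy))
  if (p_sp + p_sm > 1) {
    stop(sprintf("stable-state exit probabilities exceed 1 at cycle %d", cycle),
         call. = FALSE)
  }
  m <- matrix(0, 5, 5, dimnames = list(states, states))
  m["stable", "progression"] <- (1 - q_o) * p_sp
  m["stable", "metastatic"] <- (1 - q_o) * p_sm
  m["stable", "death_other"] <- q_o
  m["stable", "stable"] <- 1 - sum(m["stable", ])
  m["progression", "metastatic"] <- (1 - q_o) * p_pm
  m["progression", "death_other"] <- q_o
  m["progression", "progression"] <- 1 - sum(m["progression", ])
  m["metastatic", "death_pc"] <- (1 - q_o) * p_md
  m["metastatic", "death_other"] <- q_o
  m["metastatic", "metastatic"] <- 1 - sum(m["metastatic", ])
  m["death_pc", "death_pc"] <- 1
  m["death_other", "death_other"] <- 1
  m
}

#' Run the cohort through the model for one strategy
#'
#' Starts the whole cohort in the stable state at `start_age` and applies
#' the cycle-specific transition matrices up to `horizon_age`.  The trace
#' stores start-of-cycle occupancy: row 1 is age `start_age` (100% stable),
#' the last row age `horizon_age`.
#'
#' @param model A [decision_model()].
#' @param strategy Strategy label.
#' @return A `pc_cohort_trace`: a data frame with `cycle`, `age` and one
#'   occupancy column per state.
#' @export
run_cohort <- function(model, strategy) {
  stopifnot(inherits(model, "pc_decision_model"))
  n_cycles <- model$horizon_age - model$start_age
  states <- pc_states()
  cycles <- seq_len(n_cycles) - 1L
  tr <- model$transitions
  q_o <- other_cause_probability(model$life_table, model$start_age + cycles)
  p_sp <- annual_transition_probability(tr$stable_progression, cycles,
                                        arm = tr_arm(tr$stable_progression, strategy))
  p_sm <- annual_transition_probability(tr$stable_metastasis, cycles,
                                        arm = tr_arm(tr$stable_metastasis, strategy))
  p_pm <- annual_transition_probability(tr$progression_metastasis, cycles,
                                        arm = tr_arm(tr$progression_metastasis, strategy))
  p_md <- annual_transition_probability(tr$metastatic_death, cycles,
                                        arm = tr_arm(tr$metastatic_death, strategy))
  if (any(p_sp + p_sm > 1)) {
    stop(sprintf("stable-state exit probabilities exceed 1 at cycle %d",
                 cycles[which(p_sp + p_sm > 1)[1]]), call. = FALSE)
  }
  occ <- matrix(0, n_cycles + 1L, 5, dimnames = list(NULL, states))
  occ[1, "stable"] <- 1
  s <- 1; p <- 0; m <- 0; dpc <- 0; doth <- 0
  for (t in seq_len(n_cycles)) {
    q <- q_o[t]
    stay_s <- 1 - ((1 - q) * p_sp[t] + (1 - q) * p_sm[t] + q)
    stay_p <- 1 - ((1 - q) * p_pm[t] + q)
    stay_m <- 1 - ((1 - q) * p_md[t] + q)
    new_doth <- doth + (s + p + m) * q
    new_dpc <- dpc + m * (1 - q) * p_md[t]
    new_m <- m * stay_m + p * (1 - q) * p_pm[t] + s * (1 - q) * p_sm[t]
    new_p <- p * stay_p + s * (1 - q) * p_sp[t]
    new_s <- s * stay_s
    s <- new_s; p <- new_p; m <- new_m; dpc <- new_dpc; doth <- new_doth
    occ[t + 1L, ] <- c(s, p, m, dpc, doth)
  }
  tot <- rowSums(occ)
  if (any(abs(tot - 1) > 1e-10)) {
    stop("cohort occupancy is not conserved; invalid transition inputs",
         call. = FALSE)
  }
  out <- data.frame(cycle = 0:n_cycles, age = model$start_age + 0:n_cycles)
  out <- cbind(out, as.data.frame(occ))
  attr(out, "strategy") <- strategy
  class(out) <- c("pc_cohort_trace", "data.frame")
  out
}

#' @export
print.pc_cohort_trace <- function(x, ...) {
  cat(sprintf("<pc_cohort_trace> strategy %s, ages %d-%d\n",
              attr(x, "strategy"), min(x$age), max(x$age)))
  print.data.frame(head(as.data.frame(round(x, 4)), 5))
  cat("  ...", nrow(x) - 5, "more cycles\n")
  invisible(x)
}

#' Write a cohort trace as CSV
#'
#' Columns `cycle, age, p_stable, p_progression, p_metastatic, p_death_pc,
#' p_death_other`.
#'
#' @param trace A `pc_cohort_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pc_cohort_trace"))
  df <- as.data.frame(trace)
  names(df)[match(pc_states(), names(df))] <- paste0("p_", pc_states())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Undiscounted per-cycle cost and QALY increments for a strategy
#'
#' The QALY increment of cycle *t* is the utility-weighted living-state
#' occupancy; the cost increment is the strategy-specific annual state cost
#' weighted by occupancy plus the shared last-year-of-life cost times the
#' proportion of the cohort newly entering a death state during the cycle.
#' With the half-cycle correction on, occupancy-based payoffs use the mean
#' of start- and end-of-cycle occupancy; death-entry (terminal cost) flows
#' are exact and never half-cycle corrected.
#'
#' @param trace A `pc_cohort_trace` from [run_cohort()].
#' @param state_values A [state_values()] object.
#' @param strategy Strategy label (must be a column of the cost matrix).
#' @param half_cycle Apply the half-cycle correction?
#' @return A data frame with `cycle`, `qaly` and `cost` increments, one row
#'   per cycle lived (length `nrow(trace) - 1`).
#' @export
cycle_outcomes <- function(trace, state_values, strategy, half_cycle = TRUE) {
  stopifnot(inherits(trace, "pc_cohort_trace"),
            inherits(state_values, "pc_state_values"))
  if (!strategy %in% colnames(state_values$cost)) {
    stop(sprintf("no costs available for strategy '%s'", strategy),
         call. = FALSE)
  }
  states <- pc_states()
  living <- pc_living_states()
  occ <- as.matrix(as.data.frame(trace)[, states])
  n_cycles <- nrow(occ) - 1L
  u <- c(state_values$utility[living], death_pc = 0, death_other = 0)[states]
  cvec <- c(state_values$cost[living, strategy], death_pc = 0,
            death_other = 0)[states]
  start <- occ[seq_len(n_cycles), , drop = FALSE]
  end <- occ[seq_len(n_cycles) + 1L, , drop = FALSE]
  eff <- if (half_cycle) (start + end) / 2 else start
  qaly <- as.vector(eff %*% u)
  new_dead <- rowSums(end[, pc_death_states(), drop = FALSE]) -
    rowSums(start[, pc_death_states(), drop = FALSE])
  cost <- as.vector(eff %*% cvec) + state_values$terminal_cost * new_dead
  data.frame(cycle = seq_len(n_cycles) - 1L, qaly = qaly, cost = cost)
}
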