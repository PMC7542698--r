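# Health-state utilities and state/strategy annual costs, estimated from
# annual patient-level observations.  Utilities are pooled across the three
# management strategies (the strategy effect on quality of life is captured
# by the proportions entering each state); costs stay strategy-specific and
# fold the observed treatment mix into the state they are observed in.  A
# shared last-year-of-life ("terminal") cost is applied to the year of death
# regardless of strategy.

#' Impute missing annual utilities from adjacent years
#'
#' Internal gaps are filled with the mean of the nearest observed prior and
#' following values; leading and trailing gaps carry the single nearest
#' observed value.
#'
#' @param x Numeric vector with `NA` gaps; at least one observed value.
#' @return `x` with all gaps filled.
#' @export
#' @examples
#' impute_adjacent(c(0.8, NA, 0.6))   # 0.8 0.7 0.6
#' impute_adjacent(c(NA, 0.9))        # 0.9 0.9
impute_adjacent <- function(x) {
  if (length(x) == 0) return(x)
  obs <- which(!is.na(x))
  if (length(obs) == 0) {
    stop("cannot impute a fully missing utility series", call. = FALSE)
  }
  out <- x
  for (i in which(is.na(x))) {
    prior <- obs[obs < i]
    after <- obs[obs > i]
    if (length(prior) && length(after)) {
      out[i] <- (x[max(prior)] + x[min(after)]) / 2
    } else if (length(prior)) {
      out[i] <- x[max(prior)]
    } else {
      out[i] <- x[min(after)]
    }
  }
  out
}

#' Construct a set of state values (utilities and costs)
#'
#' @param utility Named numeric vector of EQ-5D-3L index utilities for the
#'   living states (`stable`, `progression`, `metastatic`); death states are
#'   fixed at utility 0 and recurring cost 0.
#' @param cost Numeric matrix of annual costs in GBP, rows = living states,
#'   columns = strategies (`AM`, `RP`, `RT`).
#' @param terminal_cost Last-year-of-life cost in GBP, shared across
#'   strategies, applied once on entry to a death state.
#' @param utility_se,cost_se,terminal_cost_se Standard errors (same shapes);
#'   default 0, meaning deterministic values.
#' @return A `pc_state_values` object.
#' @export
#' @examples
#' sv <- state_values(
#'   utility = c(stable = 0.8, progression = 0.75, metastatic = 0.65),
#'   cost = matrix(c(550, 450, 500, 1200, 1200, 1200, 5000, 5000, 5000),
#'                 nrow = 3, byrow = TRUE,
#'                 dimnames = list(pc_living_states(), pc_strategies())),
#'   terminal_cost = 3000)
state_values <- function(utility, cost, terminal_cost,
                         utility_se = NULL, cost_se = NULL,
                         terminal_cost_se = 0) {
  states <- pc_living_states()
  if (!all(states %in% names(utility))) {
    stop("utility must be named for all living states: ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  utility <- utility[states]
  if (any(utility > 1)) stop("utilities cannot exceed 1", call. = FALSE)
  if (!is.matrix(cost) || !all(states %in% rownames(cost))) {
    stop("cost must be a matrix with living states as rownames", call. = FALSE)
  }
  strategies <- colnames(cost)
  cost <- cost[states, , drop = FALSE]
  if (any(cost < 0) || terminal_cost < 0) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (is.null(utility_se)) utility_se <- setNames(rep(0, 3), states)
  if (is.null(cost_se)) {
    cost_se <- matrix(0, 3, length(strategies),
                      dimnames = list(states, strategies))
  }
  structure(
    list(utility = utility, utility_se = utility_se[states],
         cost = cost, cost_se = cost_se[states, , drop = FALSE],
         terminal_cost = terminal_cost, terminal_cost_se = terminal_cost_se,
         strategies = strategies),
    class = "pc_state_values"
  )
}

#' @export
print.pc_state_values <- function(x, ...) {
  cat("<pc_state_values>\n utilities:",
      paste(sprintf("%s=%.3f", names(x$utility), x$utility), collapse = ", "),
      "\n annual costs (GBP):\n")
  print(round(x$cost, 0))
  cat(sprintf(" terminal (last year of life) cost: %.0f\n", x$terminal_cost))
  invisible(x)
}

#' Estimate state utilities and costs from patient-level records
#'
#' Assigns each observed patient-year to the health state occupied at the
#' start of that year, imputes missing utilities from adjacent years
#' ([impute_adjacent()]), then averages: utilities per state pooled across
#' strategies, annual costs per state within strategy.  Costs observed in a
#' patient's year of death are pooled across strategies into the shared
#' terminal (last-year-of-life) cost.  Standard errors of all means are
#' returned for probabilistic sensitivity analysis.
#'
#' @param records A `pc_trial_data` object (see [generate_cohort()] /
#'   [read_trial_csv()]).
#' @return A [state_values()] object.
#' @export
estimate_state_values <- function(records) {
  stopifnot(inherits(records, "pc_trial_data"))
  states <- pc_living_states()
  strategies <- pc_strategies()
  per_patient <- lapply(seq_len(nrow(records)), function(i) {
    u <- records$utility[[i]]
    cst <- records$cost[[i]]
    ny <- length(cst)
    if (ny == 0) return(NULL)
    if (any(!is.na(u))) u <- impute_adjacent(u)
    y <- seq_len(ny) - 1L
    st <- rep("stable", ny)
    if (records$e_prog[i] == 1) st[y >= records$t_prog[i]] <- "progression"
    if (records$e_met[i] == 1) st[y >= records$t_met[i]] <- "metastatic"
    death_time <- if (records$e_pcdeath[i] == 1) records$t_pcdeath[i]
                  else if (records$e_death_other[i] == 1) records$t_death_other[i]
                  else NA_real_
    death_year <- !is.na(death_time) & death_time > y & death_time <= y + 1
    data.frame(state = st, arm = as.character(records$arm[i]),
               utility = u, cost = cst, death_year = death_year,
               stringsAsFactors = FALSE)
  })
  py <- do.call(rbind, per_patient)
  if (is.null(py)) py <- data.frame(state = character(0), arm = character(0),
                                    utility = numeric(0), cost = numeric(0),
                                    death_year = logical(0))
  util_acc <- lapply(setNames(states, states), function(s) {
    na.omit(py$utility[py$state == s])
  })
  cost_acc <- matrix(list(), 3, 3, dimnames = list(states, strategies))
  for (s in states) for (a in strategies) {
    cost_acc[[s, a]] <- na.omit(py$cost[py$state == s & py$arm == a & !py$death_year])
  }
  term_acc <- na.omit(py$cost[py$death_year])

  empty_u <- states[vapply(util_acc, length, integer(1)) == 0]
  if (length(empty_u) > 0) {
    stop("no patient-years observed in state(s): ",
         paste(empty_u, collapse = ", "), call. = FALSE)
  }
  mean_se <- function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) sd(v) / sqrt(length(v)) else 0)
  }
  um <- vapply(util_acc, mean_se, numeric(2))
  cm <- matrix(0, 3, 3, dimnames = list(states, strategies))
  cs <- cm
  for (s in states) for (a in strategies) {
    ms <- mean_se(cost_acc[[s, a]])
    if (is.na(ms[1])) {
      stop(sprintf("no patient-years observed in state '%s' for arm %s", s, a),
           call. = FALSE)
    }
    cm[s, a] <- ms[1]; cs[s, a] <- ms[2]
  }
  tm <- mean_se(term_acc)
  if (is.na(tm[1])) tm <- c(0, 0)  # nobody died within follow-up
  state_values(utility = um[1, ], utility_se = um[2, ],
               cost = cm, cost_se = cs,
               terminal_cost = tm[1], terminal_cost_se = tm[2])
}

#' Write and read state values as CSV
#'
#' Columns `state, strategy, utility, utility_se, annual_cost, cost_se`;
#' utilities repeat across the strategy rows of a state (they are pooled);
#' the shared last-year-of-life cost appears as a row with state
#' `"terminal"` and empty strategy.
#'
#' @param values A [state_values()] object.
#' @param path CSV path.
#' @return `write_state_values_csv` returns `path` invisibly;
#'   `read_state_values_csv` a [state_values()] object.
#' @export
write_state_values_csv <- function(values, path) {
  stopifnot(inherits(values, "pc_state_values"))
  rows <- expand.grid(state = pc_living_states(),
                      strategy = values$strategies,
                      stringsAsFactors = FALSE)
  rows$utility <- values$utility[rows$state]
  rows$utility_se <- values$utility_se[rows$state]
  rows$annual_cost <- values$cost[cbind(rows$state, rows$strategy)]
  rows$cost_se <- values$cost_se[cbind(rows$state, rows$strategy)]
  rows <- rbind(rows, data.frame(state = "terminal", strategy = NA,
                                 utility = 0, utility_se = 0,
                                 annual_cost = values$terminal_cost,
                                 cost_se = values$terminal_cost_se))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_state_values_csv
#' @export
read_state_values_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "strategy", "utility", "utility_se", "annual_cost", "cost_se")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("state-values CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  term <- df[df$state == "terminal", ]
  df <- df[df$state != "terminal", ]
  states <- pc_living_states()
  strategies <- sort(unique(df$strategy))
  u <- setNames(rep(NA_real_, 3), states)
  use <- u
  cm <- matrix(NA_real_, 3, length(strategies),
               dimnames = list(states, strategies))
  cs <- cm
  for (k in seq_len(nrow(df))) {
    r <- df[k, ]
    u[r$state] <- r$utility; use[r$state] <- r$utility_se
    cm[r$state, r$strategy] <- r$annual_cost
    cs[r$state, r$strategy] <- r$cost_se
  }
  if (anyNA(cm)) stop("state-values CSV has missing state/strategy cells",
                      call. = FALSE)
  state_values(utility = u, utility_se = use, cost = cm, cost_se = cs,
               terminal_cost = if (nrow(term)) term$annual_cost[1] else 0,
               terminal_cost_se = if (nrow(term)) term$cost_se[1] else 0)
}
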