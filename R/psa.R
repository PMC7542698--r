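# Probabilistic sensitivity analysis: joint Monte-Carlo sampling of all
# model inputs (survival coefficients ~ multivariate normal on the
# estimation scale using the fit covariance; utilities ~ beta; costs ~
# gamma, both moment-matched to mean and SE), propagated through the full
# cohort model; percentile confidence intervals and cost-effectiveness
# acceptability curves.

#' Configuration for probabilistic sensitivity analysis
#'
#' @param n_iterations Number of joint parameter draws (default 10000).
#' @param seed Master seed.  Per-iteration seeds are derived from it once,
#'   so any single iteration is reproducible independently of execution
#'   order.
#' @param thresholds Willingness-to-pay grid (GBP/QALY) for the CEAC;
#'   non-negative and increasing.
#' @param utility_dist `"beta"` (moment-matched; requires means strictly
#'   inside (0,1)) or `"normal"` (truncated to the EQ-5D-3L index range).
#' @param cost_dist `"gamma"` (moment-matched) or `"normal"` (truncated at
#'   0).
#' @return A `pc_psa_config`.
#' @export
psa_config <- function(n_iterations = 10000, seed = 1,
                       thresholds = seq(0, 50000, by = 1000),
                       utility_dist = c("beta", "normal"),
                       cost_dist = c("gamma", "normal")) {
  if (n_iterations < 1) stop_config("n_iterations", "must be >= 1")
  if (any(thresholds < 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop_config("thresholds", "must be non-negative and increasing")
  }
  structure(
    list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         thresholds = thresholds,
         utility_dist = match.arg(utility_dist),
         cost_dist = match.arg(cost_dist)),
    class = "pc_psa_config"
  )
}

iteration_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# moment-matched beta draw; means outside (0,1) (legal for EQ-5D) fall back
# to a truncated normal on the index range
draw_utility <- function(n, mean, se, dist) {
  if (se == 0) return(rep(mean, n))
  if (dist == "beta" && mean > 0 && mean < 1) {
    nu <- mean * (1 - mean) / se^2 - 1
    if (nu <= 0) {
      stop(sprintf("utility SE %.3g too large for a beta with mean %.3g",
                   se, mean), call. = FALSE)
    }
    rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
  } else {
    pmin(pmax(rnorm(n, mean, se), -0.594), 1)
  }
}

draw_cost <- function(n, mean, se, dist) {
  if (se == 0 || mean == 0) return(rep(mean, n))
  if (dist == "gamma") {
    rgamma(n, shape = (mean / se)^2, rate = mean / se^2)
  } else {
    pmax(rnorm(n, mean, se), 0)
  }
}

draw_transition <- function(model) {
  if (all(model$vcov == 0) || any(!is.finite(model$coefficients))) {
    return(model)
  }
  co <- MASS::mvrnorm(1, mu = model$coefficients, Sigma = model$vcov)
  model$coefficients <- setNames(as.numeric(co), names(model$coefficients))
  model
}

psa_is_degenerate <- function(model) {
  sv <- model$state_values
  all(vapply(model$transitions, function(m) all(m$vcov == 0), logical(1))) &&
    all(sv$utility_se == 0) && all(sv$cost_se == 0) && sv$terminal_cost_se == 0
}

sample_inputs_impl <- function(model, psa_cfg) {
  sv <- model$state_values
  u <- vapply(pc_living_states(), function(s) {
    draw_utility(1, sv$utility[s], sv$utility_se[s], psa_cfg$utility_dist)
  }, numeric(1))
  cm <- sv$cost
  for (s in rownames(cm)) for (a in colnames(cm)) {
    cm[s, a] <- draw_cost(1, sv$cost[s, a], sv$cost_se[s, a], psa_cfg$cost_dist)
  }
  tc <- draw_cost(1, sv$terminal_cost, sv$terminal_cost_se, psa_cfg$cost_dist)
  model$state_values <- state_values(utility = u, cost = cm, terminal_cost = tc)
  model$transitions <- lapply(model$transitions, draw_transition)
  model
}

#' Draw one joint parameter set for the PSA
#'
#' Survival coefficients are drawn multivariate normal on the estimation
#' scale using each transition fit's covariance matrix; state utilities are
#' beta and costs gamma, parameterised by the method of moments from their
#' means and standard errors.  Parameters with zero SE stay at their point
#' estimates; if every input is deterministic, a degenerate-PSA warning is
#' issued.
#'
#' @param model A [decision_model()] carrying estimation uncertainty.
#' @param psa_cfg A [psa_config()].
#' @param iteration Iteration index in 1..`n_iterations`; together with the
#'   master seed this fully determines the draw.
#' @return A [decision_model()] with sampled parameters (all SEs zeroed).
#' @export
sample_inputs <- function(model, psa_cfg, iteration) {
  stopifnot(inherits(model, "pc_decision_model"),
            inherits(psa_cfg, "pc_psa_config"))
  if (iteration < 1 || iteration > psa_cfg$n_iterations) {
    stop("iteration out of range", call. = FALSE)
  }
  if (psa_is_degenerate(model)) {
    warning("all parameter SEs are zero: PSA draws equal the deterministic inputs",
            call. = FALSE)
  }
  seeds <- iteration_seeds(psa_cfg$seed, psa_cfg$n_iterations)
  set.seed(seeds[iteration])
  sample_inputs_impl(model, psa_cfg)
}

#' Run the probabilistic sensitivity analysis
#'
#' Propagates `n_iterations` joint parameter draws through the cohort model
#' for every strategy, recording discounted lifetime cost and QALYs per
#' draw.
#'
#' @param model A [decision_model()].
#' @param psa_cfg A [psa_config()].
#' @return A `pc_psa_draws` data frame with columns `iteration, strategy,
#'   cost, qaly`.
#' @export
run_psa <- function(model, psa_cfg) {
  stopifnot(inherits(model, "pc_decision_model"),
            inherits(psa_cfg, "pc_psa_config"))
  if (psa_is_degenerate(model)) {
    warning("all parameter SEs are zero: PSA draws equal the deterministic inputs",
            call. = FALSE)
  }
  seeds <- iteration_seeds(psa_cfg$seed, psa_cfg$n_iterations)
  n_strat <- length(model$strategies)
  res <- vector("list", psa_cfg$n_iterations)
  for (i in seq_len(psa_cfg$n_iterations)) {
    set.seed(seeds[i])
    drawn <- sample_inputs_impl(model, psa_cfg)
    rows <- tryCatch({
      vapply(model$strategies, function(strat) {
        trace <- run_cohort(drawn, strat)
        out <- cycle_outcomes(trace, drawn$state_values, strat,
                              half_cycle = model$half_cycle)
        tot <- lifetime_totals(out, model$discount_rate)
        c(tot$cost, tot$qaly)
      }, numeric(2))
    }, error = function(e) {
      stop(sprintf("PSA iteration %d produced an invalid model: %s",
                   i, conditionMessage(e)), call. = FALSE)
    })
    res[[i]] <- data.frame(iteration = i, strategy = model$strategies,
                           cost = rows[1, ], qaly = rows[2, ],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "strategies") <- model$strategies
  class(out) <- c("pc_psa_draws", "data.frame")
  out
}

#' Percentile confidence interval from Monte-Carlo draws
#'
#' Empirical quantiles with linear interpolation between order statistics
#' (R quantile type 7).
#'
#' @param x Numeric draws (>= 2 values).
#' @param level Coverage (default 0.95: the 2.5th and 97.5th percentiles).
#' @return Named vector `c(lo, hi)`.
#' @export
#' @examples
#' percentile_ci(1:10000)  # c(250.975, 9750.025)
percentile_ci <- function(x, level = 0.95) {
  if (length(x) < 2) stop("need at least two draws", call. = FALSE)
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 1 - a), type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Summarise PSA draws per strategy
#'
#' Means of cost and QALYs across draws, a point NMB (by default the mean
#' of the per-draw NMBs; alternatively the NMB of the mean cost and QALYs)
#' and its percentile CI.
#'
#' @param draws A `pc_psa_draws`.
#' @param threshold Willingness to pay (GBP/QALY).
#' @param level CI coverage.
#' @param point `"mean_nmb"` or `"nmb_of_means"`.
#' @return A data frame `strategy, cost, qaly, nmb, nmb_lo, nmb_hi`.
#' @export
summarise_psa <- function(draws, threshold = 20000, level = 0.95,
                          point = c("mean_nmb", "nmb_of_means")) {
  stopifnot(inherits(draws, "pc_psa_draws"))
  point <- match.arg(point)
  strategies <- attr(draws, "strategies")
  rows <- lapply(strategies, function(strat) {
    d <- draws[draws$strategy == strat, ]
    nmb_draws <- net_monetary_benefit(d$qaly, d$cost, threshold)
    nmb_pt <- if (point == "mean_nmb") mean(nmb_draws) else {
      net_monetary_benefit(mean(d$qaly), mean(d$cost), threshold)
    }
    ci <- percentile_ci(nmb_draws, level)
    data.frame(strategy = strat, cost = mean(d$cost), qaly = mean(d$qaly),
               nmb = nmb_pt, nmb_lo = ci["lo"], nmb_hi = ci["hi"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For every threshold on the grid, the probability (fraction of PSA draws)
#' that each strategy attains the maximum net monetary benefit.  Exact ties
#' are split equally, so the probabilities sum to 1 at every threshold.
#'
#' @param draws A `pc_psa_draws`.
#' @param thresholds Willingness-to-pay grid (GBP/QALY).
#' @return A `pc_ceac` data frame `threshold, strategy, probability`.
#' @export
ceac <- function(draws, thresholds = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(draws, "pc_psa_draws"))
  strategies <- attr(draws, "strategies")
  n_iter <- max(draws$iteration)
  cost <- matrix(draws$cost[order(match(draws$strategy, strategies), draws$iteration)],
                 nrow = n_iter, ncol = length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- matrix(draws$qaly[order(match(draws$strategy, strategies), draws$iteration)],
                 nrow = n_iter, ncol = length(strategies),
                 dimnames = list(NULL, strategies))
  rows <- lapply(thresholds, function(lam) {
    nmb <- qaly * lam - cost
    best <- nmb == apply(nmb, 1, max)
    w <- best / rowSums(best)   # equal split of exact ties
    data.frame(threshold = lam, strategy = strategies,
               probability = colMeans(w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pc_ceac", "data.frame")
  out
}

#' Write PSA draws and CEAC tables as CSV
#'
#' @param x A `pc_psa_draws` or `pc_ceac`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
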