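# Discounting, lifetime totals, net monetary benefit and strategy ranking.

#' Discount a value accrued at a given cycle
#'
#' Cycle-start convention: a value accrued during cycle *t* is divided by
#' \eqn{(1 + r)^t}, so cycle 0 is undiscounted.
#'
#' @param value Value(s) to discount.
#' @param cycle Cycle index(es), >= 0.
#' @param rate Annual discount rate (default 3.5%, the UK NICE reference
#'   case).
#' @return Discounted value(s).
#' @export
#' @examples
#' discount(103.5, 1)            # 100
#' discount(100, 20)             # ~50.257
discount <- function(value, cycle, rate = 0.035) {
  if (rate <= -1) stop("discount rate must exceed -1", call. = FALSE)
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  value / (1 + rate)^cycle
}

#' Discounted lifetime totals from per-cycle increments
#'
#' @param outcomes Data frame from [cycle_outcomes()] with columns `cycle`,
#'   `qaly`, `cost`.
#' @param rate Annual discount rate.
#' @return A list with elements `cost` and `qaly`.
#' @export
lifetime_totals <- function(outcomes, rate = 0.035) {
  list(cost = sum(discount(outcomes$cost, outcomes$cycle, rate)),
       qaly = sum(discount(outcomes$qaly, outcomes$cycle, rate)))
}

#' Net monetary benefit
#'
#' \eqn{NMB = QALYs \times \lambda - cost} at willingness-to-pay threshold
#' \eqn{\lambda} per QALY gained.  The strategy with the greatest NMB is
#' deemed the most cost-effective.
#'
#' @param qalys Lifetime discounted QALYs.
#' @param cost Lifetime discounted cost (GBP).
#' @param threshold Willingness to pay per QALY (GBP; default 20000).
#' @return NMB in GBP.
#' @export
#' @examples
#' net_monetary_benefit(15.36, 15359)   # 291841
net_monetary_benefit <- function(qalys, cost, threshold = 20000) {
  if (any(threshold < 0)) stop("threshold must be >= 0", call. = FALSE)
  qalys * threshold - cost
}

#' Deterministic lifetime evaluation of all strategies
#'
#' Runs the cohort model per strategy, accumulates discounted lifetime costs
#' and QALYs, and computes net monetary benefit at the given threshold.
#'
#' @param model A [decision_model()].
#' @param threshold Willingness-to-pay threshold (GBP per QALY).
#' @return A `pc_econ_result` data frame with one row per strategy and
#'   columns `strategy, cost, qaly, nmb`.
#' @export
evaluate_model <- function(model, threshold = 20000) {
  stopifnot(inherits(model, "pc_decision_model"))
  rows <- lapply(model$strategies, function(strat) {
    trace <- run_cohort(model, strat)
    out <- cycle_outcomes(trace, model$state_values, strat,
                          half_cycle = model$half_cycle)
    tot <- lifetime_totals(out, model$discount_rate)
    data.frame(strategy = strat, cost = tot$cost, qaly = tot$qaly,
               nmb = net_monetary_benefit(tot$qaly, tot$cost, threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "threshold") <- threshold
  class(res) <- c("pc_econ_result", "data.frame")
  res
}

#' Rank strategies by net monetary benefit
#'
#' Orders strategies by descending NMB.  Exact ties break by lower cost,
#' then by strategy label.  If 95% CI columns (`nmb_lo`, `nmb_hi`) are
#' present and the best strategy's interval overlaps any other strategy's,
#' the evidence that the strategies differ is flagged as weak.
#'
#' @param results A data frame with columns `strategy`, `nmb` and optionally
#'   `cost`, `nmb_lo`, `nmb_hi`.
#' @return The rows of `results` in rank order, with attributes `best`
#'   (strategy label) and `weak_evidence` (logical, `NA` without CIs).
#' @export
rank_strategies <- function(results) {
  if (nrow(results) < 2) {
    stop("ranking needs at least two strategies", call. = FALSE)
  }
  cost <- if ("cost" %in% names(results)) results$cost else rep(0, nrow(results))
  ord <- order(-results$nmb, cost, results$strategy)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  weak <- NA
  if (all(c("nmb_lo", "nmb_hi") %in% names(results))) {
    weak <- any(out$nmb_hi[-1] >= out$nmb_lo[1])
  }
  attr(out, "best") <- out$strategy[1]
  attr(out, "weak_evidence") <- weak
  out
}

#' Write a Table-1-style results grid as CSV, and read it back
#'
#' Columns `subgroup, strategy, mean_cost, mean_qaly, nmb, nmb_lo, nmb_hi`.
#'
#' @param results Data frame with those columns (CI columns may be `NA`).
#' @param path CSV path.
#' @return `write_results_csv` returns `path` invisibly; `read_results_csv`
#'   the parsed data frame.
#' @export
write_results_csv <- function(results, path) {
  need <- c("subgroup", "strategy", "mean_cost", "mean_qaly", "nmb",
            "nmb_lo", "nmb_hi")
  for (cl in setdiff(need, names(results))) results[[cl]] <- NA_real_
  write.csv(results[, need], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subgroup", "strategy", "mean_cost", "mean_qaly", "nmb")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("results CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
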