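# End-to-end analysis: fit all four disease transitions from patient-level
# data (with AIC family selection), estimate state values, run the cohort
# model per strategy, and summarise deterministically and probabilistically,
# overall or within age / risk subgroups.

#' Fit all four disease transitions from patient-level data
#'
#' Derives the censored duration and event indicator for each model edge
#' from the trial columns, fits both Weibull and exponential families and
#' keeps the lower-AIC fit per edge ([select_family()]).  The randomised
#' arm enters as a proportional-hazards covariate on the two stable-state
#' exits; the progression-to-metastasis and metastasis-to-death hazards are
#' shared across arms.
#'
#' Edge derivation: the time at risk of leaving the stable state is
#' `t_prog` (identical to the progression and direct-metastasis exit time);
#' local progression and direct metastasis are competing events.  Men who
#' progress contribute `t_met - t_prog` to the progression-to-metastasis
#' edge; men with metastases contribute `t_pcdeath - t_met` to the
#' metastasis-to-death edge.
#'
#' @param records A `pc_trial_data`.
#' @param arm_covariate Fit the stable-state exits with the arm covariate?
#' @return Named list of four `pc_transition_model` objects
#'   (`stable_progression`, `stable_metastasis`, `progression_metastasis`,
#'   `metastatic_death`).
#' @export
fit_all_transitions <- function(records, arm_covariate = TRUE) {
  stopifnot(inherits(records, "pc_trial_data"))
  fit_edge <- function(time, event, arm, label) {
    keep <- time > 0
    time <- time[keep]; event <- event[keep]
    if (!is.null(arm)) arm <- droplevels(factor(arm[keep], levels = pc_strategies()))
    both <- lapply(c("weibull", "exponential"), function(fam) {
      fit_transition(time, event, fam, arm = arm, transition = label)
    })
    select_family(both[[1]], both[[2]])
  }
  arm <- if (arm_covariate) records$arm else NULL
  prog <- records$e_prog == 1
  met <- records$e_met == 1
  list(
    stable_progression = fit_edge(records$t_prog, records$e_prog, arm,
                                  "stable_progression"),
    stable_metastasis = fit_edge(records$t_prog,
                                 as.integer(met & !prog), arm,
                                 "stable_metastasis"),
    progression_metastasis = fit_edge(records$t_met[prog] - records$t_prog[prog],
                                      records$e_met[prog], NULL,
                                      "progression_metastasis"),
    metastatic_death = fit_edge(records$t_pcdeath[met] - records$t_met[met],
                                records$e_pcdeath[met], NULL,
                                "metastatic_death")
  )
}

#' Full cost-effectiveness analysis of one cohort
#'
#' The complete pipeline: fit transitions ([fit_all_transitions()]),
#' estimate state values ([estimate_state_values()]), assemble the
#' [decision_model()], evaluate it deterministically and (optionally) run
#' the probabilistic sensitivity analysis with percentile CIs and CEACs.
#'
#' @param records A `pc_trial_data` (from [generate_cohort()] or
#'   [read_trial_csv()]).
#' @param life_table A [life_table()]; default the shipped synthetic
#'   UK-shaped table.
#' @param threshold Willingness to pay (GBP/QALY, default 20000).
#' @param psa A [psa_config()], or `NULL` to skip the PSA.
#' @param start_age,horizon_age,discount_rate,half_cycle Passed to
#'   [decision_model()].
#' @return A `pc_cea` list with elements `model`, `deterministic`
#'   (per-strategy cost/QALY/NMB), and when the PSA runs also `draws`,
#'   `psa_summary`, `ceac` and a Table-1-style `results` grid
#'   (deterministic means with probabilistic NMB and percentile CI).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(generator_config(n_per_arm = 150, seed = 7))
#' cea <- evaluate_strategies(cohort, psa = NULL)
#' cea$deterministic
#' }
evaluate_strategies <- function(records, life_table = default_life_table(),
                                threshold = 20000, psa = NULL,
                                start_age = 50, horizon_age = 100,
                                discount_rate = 0.035, half_cycle = TRUE) {
  transitions <- fit_all_transitions(records)
  sv <- estimate_state_values(records)
  model <- decision_model(transitions, life_table, sv,
                          start_age = start_age, horizon_age = horizon_age,
                          discount_rate = discount_rate,
                          half_cycle = half_cycle)
  det <- evaluate_model(model, threshold)
  out <- list(model = model, deterministic = det, threshold = threshold)
  if (!is.null(psa)) {
    stopifnot(inherits(psa, "pc_psa_config"))
    draws <- run_psa(model, psa)
    summ <- summarise_psa(draws, threshold)
    out$draws <- draws
    out$psa_summary <- summ
    out$ceac <- ceac(draws, psa$thresholds)
    out$results <- data.frame(
      strategy = det$strategy,
      mean_cost = det$cost, mean_qaly = det$qaly,
      nmb = summ$nmb[match(det$strategy, summ$strategy)],
      nmb_lo = summ$nmb_lo[match(det$strategy, summ$strategy)],
      nmb_hi = summ$nmb_hi[match(det$strategy, summ$strategy)],
      stringsAsFactors = FALSE)
  } else {
    out$results <- data.frame(strategy = det$strategy,
                              mean_cost = det$cost, mean_qaly = det$qaly,
                              nmb = det$nmb, nmb_lo = NA_real_,
                              nmb_hi = NA_real_, stringsAsFactors = FALSE)
  }
  class(out) <- "pc_cea"
  out
}

#' @export
print.pc_cea <- function(x, ...) {
  cat(sprintf("<pc_cea> threshold GBP %s per QALY\n",
              format(x$threshold, big.mark = ",")))
  df <- x$results
  df$mean_cost <- round(df$mean_cost)
  df$mean_qaly <- round(df$mean_qaly, 2)
  df$nmb <- round(df$nmb)
  best <- rank_strategies(x$results)
  print.data.frame(df, row.names = FALSE)
  cat("most cost-effective strategy:", attr(best, "best"), "\n")
  if (isTRUE(attr(best, "weak_evidence"))) {
    cat("note: 95% CIs overlap; evidence of a difference is weak\n")
  }
  invisible(x)
}

#' Intention-to-treat analyses stratified by age or risk subgroup
#'
#' Splits the cohort on a subgroup label (`age_band`, `damico` or
#' `grade_group`), refits all transition models and state values within
#' each stratum, and stacks the per-stratum results grids.
#'
#' @param records A `pc_trial_data`.
#' @param by Subgroup column name.
#' @param ... Passed to [evaluate_strategies()].
#' @return A data frame: the Table-1-style results grid with a `subgroup`
#'   column, plus attribute `analyses` (the per-stratum `pc_cea` objects).
#' @export
stratified_analysis <- function(records,
                                by = c("age_band", "damico", "grade_group"),
                                ...) {
  by <- match.arg(by)
  levels <- sort(unique(records[[by]]))
  analyses <- list()
  rows <- lapply(levels, function(lv) {
    sub <- records[records[[by]] == lv, , drop = FALSE]
    class(sub) <- c("pc_trial_data", "data.frame")
    cea <- evaluate_strategies(sub, ...)
    analyses[[lv]] <<- cea
    cbind(subgroup = paste(by, lv, sep = ":"), cea$results)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "analyses") <- analyses
  out
}
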