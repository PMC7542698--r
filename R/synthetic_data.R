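# Synthetic patient-level trial data with the statistical structure the
# downstream analysis assumes: three randomised arms, entry ages 50-69,
# competing Weibull exits from the stable state (local progression,
# metastasis) with arm and risk-group proportional hazards, exponential
# progression-to-metastasis and metastasis-to-prostate-cancer-death times,
# other-cause death drawn from a cause-deleted life table, administrative
# censoring around a 10-year median follow-up, and state-dependent annual
# EQ-5D-3L utilities and NHS costs with missingness.

#' Configuration for the synthetic trial-data generator
#'
#' Defaults emulate the conditions of a three-arm localised prostate cancer
#' trial with median 10-year follow-up: 545 men per arm aged 50-69 at entry;
#' on active monitoring roughly a quarter progress locally and ~6% develop
#' metastases by 10 years, with radical arms at roughly half those hazards;
#' metastatic disease carries a median survival of about 2.8 years.
#'
#' @param n_per_arm Men randomised per arm (>= 0).
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @param entry_age_range Inclusive integer age range at entry (years).
#' @param followup_median,followup_spread Administrative censoring is drawn
#'   uniformly on `followup_median` +/- `followup_spread` years.
#' @param shape_progression,scale_progression Weibull shape/scale (years) for
#'   the reference-arm stable-to-progression time.
#' @param shape_metastasis,scale_metastasis Ditto for stable-to-metastasis.
#' @param hr_arm Named hazard ratios on both stable-state exits per arm,
#'   reference AM = 1.
#' @param hr_risk Hazard ratio on stable-state exits for D'Amico
#'   intermediate/high-risk men (1 = homogeneous cohort).
#' @param p_damico_high Prevalence of D'Amico intermediate/high risk.
#' @param p_gg2_given_high,p_gg2_given_low Probability of Grade group >= 2
#'   within each D'Amico stratum.
#' @param rate_prog_met Exponential rate per year, progression to metastasis.
#' @param rate_met_death Exponential rate per year, metastasis to
#'   prostate-cancer death.
#' @param utility_mean,utility_sd Named per-state annual utility mean/SD
#'   (EQ-5D-3L index units; draws truncated to \[-0.594, 1\]).
#' @param cost_mean,cost_sd Matrices (living state x arm) of annual cost
#'   mean/SD in GBP (draws truncated at 0).
#' @param terminal_cost_mean,terminal_cost_sd Last-year-of-life cost (GBP),
#'   shared across arms.
#' @param missing_utility_prob Probability each annual utility is missing.
#' @param allow_direct_metastasis If `FALSE`, metastasis only via local
#'   progression (the stable-to-metastasis edge is switched off).
#' @param life_table A [life_table()] for other-cause death; default the
#'   shipped synthetic UK-shaped table.
#' @return A `pc_generator_config`.
#' @export
generator_config <- function(n_per_arm = 545,
                             seed = 1,
                             entry_age_range = c(50, 69),
                             followup_median = 10,
                             followup_spread = 2,
                             shape_progression = 1.3,
                             scale_progression = 25,
                             shape_metastasis = 1.3,
                             scale_metastasis = 85,
                             hr_arm = c(AM = 1, RP = 0.45, RT = 0.45),
                             hr_risk = 2,
                             p_damico_high = 0.44,
                             p_gg2_given_high = 0.45,
                             p_gg2_given_low = 0.05,
                             rate_prog_met = 0.10,
                             rate_met_death = 0.25,
                             utility_mean = c(stable = 0.80,
                                              progression = 0.75,
                                              metastatic = 0.65),
                             utility_sd = c(stable = 0.15,
                                            progression = 0.18,
                                            metastatic = 0.10),
                             cost_mean = NULL,
                             cost_sd = NULL,
                             terminal_cost_mean = 3000,
                             terminal_cost_sd = 600,
                             missing_utility_prob = 0.10,
                             allow_direct_metastasis = TRUE,
                             life_table = NULL) {
  states <- pc_living_states()
  arms <- pc_strategies()
  if (is.null(cost_mean)) {
    cost_mean <- matrix(c(550, 450, 500,
                          1200, 1200, 1200,
                          5000, 5000, 5000),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(states, arms))
  }
  if (is.null(cost_sd)) cost_sd <- 0.2 * cost_mean
  if (is.null(life_table)) life_table <- default_life_table()

  if (n_per_arm < 0) stop_config("n_per_arm", "must be >= 0")
  if (length(entry_age_range) != 2 || entry_age_range[1] > entry_age_range[2]) {
    stop_config("entry_age_range", "must be an increasing pair of ages")
  }
  if (entry_age_range[1] < min(life_table$age)) {
    stop_config("entry_age_range", "starts below the life table's range")
  }
  for (f in c("shape_progression", "shape_metastasis")) {
    if (get(f) <= 0) stop_config(f, "must be > 0")
  }
  for (f in c("scale_progression", "scale_metastasis")) {
    if (get(f) <= 0) stop_config(f, "must be > 0")
  }
  for (f in c("rate_prog_met", "rate_met_death")) {
    if (any(get(f) < 0)) stop_config(f, "must be >= 0")
  }
  if (!all(arms %in% names(hr_arm))) {
    stop_config("hr_arm", "must name all arms AM, RP, RT")
  }
  if (any(hr_arm < 0) || hr_risk < 0) stop_config("hr_arm", "must be >= 0")
  if (!all(states %in% names(utility_mean))) {
    stop_config("utility_mean", "must name all living states")
  }
  if (any(utility_mean > 1)) stop_config("utility_mean", "must be <= 1")
  if (any(utility_sd < 0)) stop_config("utility_sd", "must be >= 0")
  if (any(cost_mean < 0) || terminal_cost_mean < 0) {
    stop_config("cost_mean", "must be >= 0")
  }
  if (any(cost_sd < 0) || terminal_cost_sd < 0) {
    stop_config("cost_sd", "must be >= 0")
  }
  if (missing_utility_prob < 0 || missing_utility_prob > 1) {
    stop_config("missing_utility_prob", "must be a probability")
  }
  if (followup_median - followup_spread < 0) {
    stop_config("followup_spread", "implies negative follow-up")
  }
  rate_pm <- rep_len(unname(rate_prog_met), 3)
  rate_md <- rep_len(unname(rate_met_death), 3)
  structure(
    list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
         entry_age_range = as.integer(entry_age_range),
         followup_median = followup_median, followup_spread = followup_spread,
         shape_progression = shape_progression,
         scale_progression = scale_progression,
         shape_metastasis = shape_metastasis,
         scale_metastasis = scale_metastasis,
         hr_arm = hr_arm[arms], hr_risk = hr_risk,
         p_damico_high = p_damico_high,
         p_gg2_given_high = p_gg2_given_high,
         p_gg2_given_low = p_gg2_given_low,
         rate_prog_met = setNames(rate_pm, arms),
         rate_met_death = setNames(rate_md, arms),
         utility_mean = utility_mean[states], utility_sd = utility_sd[states],
         cost_mean = cost_mean[states, arms, drop = FALSE],
         cost_sd = cost_sd[states, arms, drop = FALSE],
         terminal_cost_mean = terminal_cost_mean,
         terminal_cost_sd = terminal_cost_sd,
         missing_utility_prob = missing_utility_prob,
         allow_direct_metastasis = isTRUE(allow_direct_metastasis),
         life_table = life_table),
    class = "pc_generator_config"
  )
}

# age at other-cause death for one man entering at `age`, as years since
# entry; death uniform within the year it occurs; Inf if he outlives the table
draw_other_cause_death <- function(lt, age) {
  ages <- lt$age
  i <- match(age, ages)
  years <- 0
  while (!is.na(i) && i <= length(ages)) {
    if (runif(1) < lt$q_other[i]) return(years + runif(1))
    years <- years + 1
    i <- i + 1
  }
  Inf
}

#' Generate a synthetic three-arm trial cohort
#'
#' Draws latent disease paths per man (competing Weibull stable-state exits,
#' then exponential onward times, with other-cause death competing
#' throughout), applies administrative censoring, and attaches annual
#' utility/cost observations via [generate_annual_observations()].  The
#' disease-path ordering (progression before metastasis before
#' prostate-cancer death on any path passing through them) holds by
#' construction.
#'
#' @param config A [generator_config()].
#' @return A `pc_trial_data` data frame, one row per man, with columns
#'   `patient_id, arm, entry_age, age_band, damico, grade_group, t_prog,
#'   e_prog, t_met, e_met, t_pcdeath, e_pcdeath, t_death_other,
#'   e_death_other, t_censor` and list columns `utility`, `cost` (annual
#'   observations, year 0 = year of entry).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_per_arm = 20, seed = 42))
#' table(cohort$arm)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "pc_generator_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  if (n == 0) return(empty_trial_data())
  arms <- rep(pc_strategies(), each = n)
  N <- 3L * n
  entry_age <- sample(seq(config$entry_age_range[1], config$entry_age_range[2]),
                      N, replace = TRUE)
  damico <- ifelse(runif(N) < config$p_damico_high, "intermediate_high", "low")
  p_gg2 <- ifelse(damico == "intermediate_high",
                  config$p_gg2_given_high, config$p_gg2_given_low)
  grade_group <- ifelse(runif(N) < p_gg2, "2plus", "1")
  admin <- runif(N, config$followup_median - config$followup_spread,
                 config$followup_median + config$followup_spread)

  hr <- unname(config$hr_arm[arms]) *
    ifelse(damico == "intermediate_high", config$hr_risk, 1)
  # latent competing exits from the stable state (hr = 0 switches an edge off)
  t_sp <- ifelse(hr > 0,
                 rweibull(N, config$shape_progression,
                          config$scale_progression * ifelse(hr > 0, hr, 1)^(-1 / config$shape_progression)),
                 Inf)
  t_sm <- if (config$allow_direct_metastasis) {
    ifelse(hr > 0,
           rweibull(N, config$shape_metastasis,
                    config$scale_metastasis * ifelse(hr > 0, hr, 1)^(-1 / config$shape_metastasis)),
           Inf)
  } else rep(Inf, N)
  rate_pm <- unname(config$rate_prog_met[arms])
  rate_md <- unname(config$rate_met_death[arms])
  t_pm <- ifelse(rate_pm > 0, rexp(N, ifelse(rate_pm > 0, rate_pm, 1)), Inf)
  t_md <- ifelse(rate_md > 0, rexp(N, ifelse(rate_md > 0, rate_md, 1)), Inf)
  ocd_time <- vapply(seq_len(N), function(i) {
    draw_other_cause_death(config$life_table, entry_age[i])
  }, numeric(1))
  # realised disease path: progression first unless direct metastasis wins
  direct <- t_sm < t_sp
  prog_time <- ifelse(direct, Inf, t_sp)
  met_time <- ifelse(direct, t_sm, t_sp + t_pm)
  pcd_time <- met_time + t_md
  end <- pmin(admin, ocd_time, pcd_time)
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(N)),
    arm = factor(arms, levels = pc_strategies()),
    entry_age = entry_age,
    age_band = ifelse(entry_age < 65, "<65", ">=65"),
    damico = damico, grade_group = grade_group,
    t_prog = pmin(prog_time, met_time, end),
    e_prog = as.integer(prog_time <= end),
    t_met = pmin(met_time, end),
    e_met = as.integer(met_time <= end),
    t_pcdeath = pmin(pcd_time, end),
    e_pcdeath = as.integer(pcd_time <= end),
    t_death_other = pmin(ocd_time, end),
    e_death_other = as.integer(ocd_time <= end),
    t_censor = end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pc_trial_data", "data.frame")
  generate_annual_observations(out, config)
}

empty_trial_data <- function() {
  out <- data.frame(patient_id = character(0), arm = factor(character(0),
                    levels = pc_strategies()),
                    entry_age = integer(0), age_band = character(0),
                    damico = character(0), grade_group = character(0),
                    t_prog = numeric(0), e_prog = integer(0),
                    t_met = numeric(0), e_met = integer(0),
                    t_pcdeath = numeric(0), e_pcdeath = integer(0),
                    t_death_other = numeric(0), e_death_other = integer(0),
                    t_censor = numeric(0), stringsAsFactors = FALSE)
  out$utility <- list()
  out$cost <- list()
  class(out) <- c("pc_trial_data", "data.frame")
  out
}

#' Attach annual utility and cost observations to a cohort
#'
#' One observation per whole year under follow-up (year 0 = year of entry),
#' assigned from the health state occupied at the start of that year, with
#' configured Gaussian noise; utilities are truncated to the EQ-5D-3L index
#' range \[-0.594, 1\] and missing with the configured probability; costs are
#' truncated at 0.  The cost of a man's year of death is drawn from the
#' shared last-year-of-life cost.  No observations extend beyond censoring
#' or death.
#'
#' @param records A `pc_trial_data` with event times drawn.
#' @param config The [generator_config()] used (for means, SDs, missingness).
#' @return `records` with `utility` and `cost` list columns filled.
#' @export
generate_annual_observations <- function(records, config) {
  stopifnot(inherits(records, "pc_trial_data"),
            inherits(config, "pc_generator_config"))
  n <- nrow(records)
  utility <- vector("list", n)
  cost <- vector("list", n)
  for (i in seq_len(n)) {
    end <- records$t_censor[i]
    ny <- if (end > 0) as.integer(ceiling(end)) else 0L
    u <- rep(NA_real_, ny)
    cs <- rep(NA_real_, ny)
    if (ny > 0) {
      death_time <- if (records$e_pcdeath[i] == 1) records$t_pcdeath[i]
                    else if (records$e_death_other[i] == 1) records$t_death_other[i]
                    else Inf
      y <- seq_len(ny) - 1L
      st <- rep("stable", ny)
      if (records$e_prog[i] == 1) st[y >= records$t_prog[i]] <- "progression"
      if (records$e_met[i] == 1) st[y >= records$t_met[i]] <- "metastatic"
      u <- pmin(pmax(rnorm(ny, config$utility_mean[st],
                           config$utility_sd[st]), -0.594), 1)
      arm <- as.character(records$arm[i])
      cs <- pmax(rnorm(ny, config$cost_mean[cbind(st, arm)],
                       config$cost_sd[cbind(st, arm)]), 0)
      death_year <- which(death_time > y & death_time <= y + 1)
      if (length(death_year) == 1L) {
        cs[death_year] <- max(rnorm(1, config$terminal_cost_mean,
                                    config$terminal_cost_sd), 0)
      }
      if (config$missing_utility_prob > 0) {
        u[runif(ny) < config$missing_utility_prob] <- NA_real_
      }
    }
    utility[[i]] <- u
    cost[[i]] <- cs
  }
  records$utility <- utility
  records$cost <- cost
  records
}

#' @export
print.pc_trial_data <- function(x, ...) {
  cat(sprintf("<pc_trial_data> %d patients (%s)\n", nrow(x),
              paste(sprintf("%s: %d", levels(x$arm), table(x$arm)),
                    collapse = ", ")))
  if (nrow(x) > 0) {
    cat(sprintf("  events: %d progression, %d metastasis, %d PC death, %d other death\n",
                sum(x$e_prog), sum(x$e_met), sum(x$e_pcdeath),
                sum(x$e_death_other)))
  }
  invisible(x)
}
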