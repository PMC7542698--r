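# Cause-deleted life tables: age-specific annual probabilities of death from
# causes other than prostate cancer (ICD-10 C61), derived from a national
# all-cause life table by removing the C61 share of deaths.

#' Cause-deleted annual death probability
#'
#' Removes deaths from a specific cause (here prostate cancer, ICD-10 C61)
#' from an all-cause annual death probability using the proportional-hazards
#' (Chiang-style) cause-deletion formula
#' \deqn{q_{other} = 1 - (1 - q_{all})^{(d_{all} - d_{C61})/d_{all}},}
#' which guarantees \eqn{0 \le q_{other} \le q_{all}}.  Simple subtraction of
#' probabilities does not.
#'
#' @param q_all Annual all-cause death probability, in \[0, 1\]. Vectorised.
#' @param deaths_all Total deaths at that age (count, > 0 unless `q_all` is 0).
#' @param deaths_c61 Deaths coded to ICD-10 C61 at that age
#'   (0 <= `deaths_c61` <= `deaths_all`).
#' @return Annual probability of death from causes other than C61.
#' @export
#' @examples
#' cause_deleted_probability(0.02, 1000, 50)   # ~0.019012
#' cause_deleted_probability(0.02, 1000, 0)    # no deletion: 0.02
cause_deleted_probability <- function(q_all, deaths_all, deaths_c61) {
  if (any(q_all < 0 | q_all > 1)) {
    stop("q_all must lie in [0, 1]", call. = FALSE)
  }
  if (any(deaths_c61 < 0) || any(deaths_all < 0)) {
    stop("death counts must be non-negative", call. = FALSE)
  }
  if (any(deaths_c61 > deaths_all)) {
    stop("deaths_c61 cannot exceed deaths_all", call. = FALSE)
  }
  if (any(deaths_all == 0 & q_all > 0)) {
    stop("deaths_all is 0 at an age where q_all > 0; cannot apportion cause",
         call. = FALSE)
  }
  n <- max(length(q_all), length(deaths_all), length(deaths_c61))
  q_all <- rep_len(q_all, n)
  deaths_all <- rep_len(deaths_all, n)
  deaths_c61 <- rep_len(deaths_c61, n)
  frac <- ifelse(deaths_all == 0, 1, (deaths_all - deaths_c61) / deaths_all)
  out <- 1 - (1 - q_all)^frac
  out[deaths_c61 == 0] <- q_all[deaths_c61 == 0]  # exact when nothing removed
  out
}

#' Construct a cause-deleted life table
#'
#' @param age Integer ages (years), contiguous over the model range.
#' @param q_all Annual all-cause death probability per age.
#' @param deaths_all Total deaths per age.
#' @param deaths_c61 Prostate-cancer (ICD-10 C61) deaths per age.
#' @return A `pc_life_table`: a data frame with the input columns plus the
#'   derived `q_other` (annual other-cause death probability).
#' @seealso [load_life_table()], [other_cause_probability()]
#' @export
life_table <- function(age, q_all, deaths_all, deaths_c61) {
  n <- length(age)
  if (length(q_all) != n || length(deaths_all) != n || length(deaths_c61) != n) {
    stop("all life-table columns must have the same length", call. = FALSE)
  }
  if (n == 0L) stop("life table is empty", call. = FALSE)
  age <- as.integer(age)
  ord <- order(age)
  age <- age[ord]; q_all <- q_all[ord]
  deaths_all <- deaths_all[ord]; deaths_c61 <- deaths_c61[ord]
  if (any(diff(age) != 1L)) {
    stop("life-table ages must be contiguous (step of 1 year)", call. = FALSE)
  }
  q_other <- cause_deleted_probability(q_all, deaths_all, deaths_c61)
  out <- data.frame(age = age, q_all = q_all, deaths_all = deaths_all,
                    deaths_c61 = deaths_c61, q_other = q_other)
  class(out) <- c("pc_life_table", "data.frame")
  out
}

#' Load a life table from CSV
#'
#' Expects columns `age, q_all, deaths_all, deaths_c61`; validates bounds,
#' contiguity of ages and count consistency, then derives `q_other`.
#'
#' @param path Path to the CSV file.
#' @return A [life_table()] object.
#' @export
load_life_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "q_all", "deaths_all", "deaths_c61")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("life-table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  life_table(df$age, df$q_all, df$deaths_all, df$deaths_c61)
}

#' Other-cause death probability at a given age
#'
#' @param table A [life_table()].
#' @param age Age(s) in whole years; must be within the table's range.
#' @return `q_other` at the requested age(s).
#' @export
other_cause_probability <- function(table, age) {
  stopifnot(inherits(table, "pc_life_table"))
  idx <- match(as.integer(age), table$age)
  if (anyNA(idx)) {
    bad <- age[is.na(idx)]
    stop(sprintf("age %s outside life-table range [%d, %d]",
                 paste(bad, collapse = ", "),
                 min(table$age), max(table$age)), call. = FALSE)
  }
  table$q_other[idx]
}

#' Synthetic UK-2014-shaped male life table
#'
#' A synthetic stand-in for a UK national male period life table around 2014:
#' Gompertz-shaped all-cause mortality over ages 50 to 100 with a humped
#' prostate-cancer (C61) share of deaths peaking near age 80.  It is *not*
#' ONS data; it reproduces the qualitative shape (other-cause mortality
#' increasing steeply with age) needed by the cohort model and tests.
#'
#' @param ages Integer ages to tabulate (default 50:100).
#' @param radix Starting cohort size used to derive death counts.
#' @return A [life_table()] object.
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' head(lt)
synthetic_life_table <- function(ages = 50:100, radix = 100000) {
  ages <- as.integer(ages)
  # Gompertz all-cause hazard calibrated to UK male levels:
  # q ~ 0.003 at 50, ~0.05 at 80, ~0.33 at 100
  q_all <- pmin(0.003 * exp(0.094 * (ages - 50)), 0.99)
  # C61 share of male deaths: ~2% at 50, peaking ~6% near 80
  share <- 0.02 + 0.04 * exp(-((ages - 80) / 12)^2)
  alive <- radix
  deaths_all <- integer(length(ages))
  for (i in seq_along(ages)) {
    deaths_all[i] <- max(1L, round(alive * q_all[i]))
    alive <- alive - deaths_all[i]
  }
  deaths_c61 <- pmin(deaths_all, round(share * deaths_all))
  life_table(ages, q_all, deaths_all, deaths_c61)
}

#' Default life table shipped with the package
#'
#' Loads the synthetic UK-2014-shaped male life-table fixture from
#' `inst/extdata/synthetic_uk_lifetable_2014.csv` (identical to the output
#' of [synthetic_life_table()] at its defaults).
#'
#' @return A [life_table()] object covering ages 50 to 100.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "synthetic_uk_lifetable_2014.csv",
                      package = "pcmarkov", mustWork = TRUE)
  load_life_table(path)
}

#' @export
print.pc_life_table <- function(x, ...) {
  cat(sprintf("<pc_life_table> ages %d-%d, q_other %.5f-%.5f\n",
              min(x$age), max(x$age), min(x$q_other), max(x$q_other)))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more rows\n")
  invisible(x)
}
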