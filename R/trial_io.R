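# Trial data CSV round-trip: one row per patient, wide annual observation
# columns util_y0..util_yK / cost_y0..cost_yK (empty cell = missing utility
# or beyond that patient's follow-up).

trial_scalar_cols <- function() {
  c("patient_id", "arm", "entry_age", "age_band", "damico", "grade_group",
    "t_prog", "e_prog", "t_met", "e_met", "t_pcdeath", "e_pcdeath",
    "t_death_other", "e_death_other", "t_censor")
}

#' Write and read patient-level trial data as CSV
#'
#' One row per patient with columns `patient_id, arm, entry_age, age_band,
#' damico, grade_group, t_prog, e_prog, t_met, e_met, t_pcdeath, e_pcdeath,
#' t_death_other, e_death_other, t_censor, util_y0..util_yK,
#' cost_y0..cost_yK`.  A missing utility is an empty cell; years beyond a
#' patient's follow-up have both utility and cost empty.  The round trip is
#' lossless.
#'
#' @param records A `pc_trial_data` object.
#' @param path CSV path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv` a
#'   `pc_trial_data` object.
#' @export
write_trial_csv <- function(records, path) {
  stopifnot(inherits(records, "pc_trial_data"))
  df <- as.data.frame(records)[, trial_scalar_cols(), drop = FALSE]
  K <- if (nrow(records) > 0) max(vapply(records$cost, length, integer(1)), 0L) else 0L
  if (K > 0) {
    for (y in seq_len(K) - 1L) {
      df[[paste0("util_y", y)]] <-
        vapply(records$utility, function(u) if (length(u) > y) u[y + 1L] else NA_real_,
               numeric(1))
    }
    for (y in seq_len(K) - 1L) {
      df[[paste0("cost_y", y)]] <-
        vapply(records$cost, function(cc) if (length(cc) > y) cc[y + 1L] else NA_real_,
               numeric(1))
    }
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- trial_scalar_cols()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trial CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("entry_age", "t_prog", "e_prog", "t_met", "e_met",
                "t_pcdeath", "e_pcdeath", "t_death_other", "e_death_other",
                "t_censor",
                grep("^(util|cost)_y[0-9]+$", names(df), value = TRUE))
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("trial CSV parse error at line %d: column '%s' value '%s' is not numeric",
                   bad[1] + 1L, cl, raw[bad[1]]), call. = FALSE)
    }
    val[!nzchar(raw)] <- NA_real_
    df[[cl]] <- val
  }
  bad_arm <- which(!df$arm %in% pc_strategies())
  if (length(bad_arm) > 0) {
    stop(sprintf("trial CSV parse error at line %d: unknown arm '%s'",
                 bad_arm[1] + 1L, df$arm[bad_arm[1]]), call. = FALSE)
  }
  util_cols <- grep("^util_y[0-9]+$", names(df), value = TRUE)
  cost_cols <- grep("^cost_y[0-9]+$", names(df), value = TRUE)
  ord <- function(cols, prefix) {
    cols[order(as.integer(sub(paste0("^", prefix, "_y"), "", cols)))]
  }
  util_cols <- ord(util_cols, "util")
  cost_cols <- ord(cost_cols, "cost")
  out <- df[, need, drop = FALSE]
  out$arm <- factor(out$arm, levels = pc_strategies())
  for (cl in c("entry_age", "e_prog", "e_met", "e_pcdeath", "e_death_other")) {
    out[[cl]] <- as.integer(out[[cl]])
  }
  umat <- as.matrix(df[, util_cols, drop = FALSE])
  cmat <- as.matrix(df[, cost_cols, drop = FALSE])
  out$utility <- vector("list", nrow(df))
  out$cost <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    crow <- if (length(cost_cols)) cmat[i, ] else numeric(0)
    present <- which(!is.na(crow))
    ny <- if (length(present)) max(present) else 0L
    out$cost[[i]] <- unname(crow[seq_len(ny)])
    urow <- if (length(util_cols)) umat[i, ] else numeric(0)
    out$utility[[i]] <- unname(urow[seq_len(ny)])
  }
  class(out) <- c("pc_trial_data", "data.frame")
  out
}
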