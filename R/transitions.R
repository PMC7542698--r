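# Parametric transition models for the cohort model's four disease edges.
#
# Each transition carries a Weibull or exponential hazard, parameterised by
# its cumulative hazard H(t) = (t / sigma)^kappa (exponential = kappa 1,
# rate lambda = 1 / sigma).  Fits are maximum likelihood under right
# censoring via survival::survreg; the estimation-scale coefficient vector
# and its covariance are retained so probabilistic sensitivity analysis can
# draw from the joint sampling distribution.  The estimation scale is
# (log_scale [, arm coefficients on the AFT scale] [, log_shape]).

new_transition_model <- function(family, coefficients, vcov, transition,
                                 arm_levels = NULL, loglik = NA_real_,
                                 n = NA_integer_, n_events = NA_integer_,
                                 data_hash = NA_character_) {
  k <- length(coefficients)
  if (is.null(vcov)) vcov <- matrix(0, k, k, dimnames = list(names(coefficients),
                                                             names(coefficients)))
  stopifnot(is.matrix(vcov), nrow(vcov) == k, ncol(vcov) == k)
  if (max(abs(vcov - t(vcov))) > 1e-8) {
    stop("parameter covariance matrix must be symmetric", call. = FALSE)
  }
  aic <- if (is.na(loglik)) NA_real_ else -2 * loglik + 2 * k
  structure(
    list(family = family, coefficients = coefficients, vcov = vcov,
         transition = transition, arm_levels = arm_levels,
         loglik = loglik, aic = aic, n = n, n_events = n_events,
         data_hash = data_hash),
    class = "pc_transition_model"
  )
}

#' Construct a transition model from known parameters
#'
#' Builds a Weibull or exponential transition hazard directly from natural
#' scale parameters, e.g. when transcribing a published parameter table
#' rather than fitting patient-level data.  The cumulative hazard is
#' \eqn{H(t) = (t/\sigma)^\kappa} for the Weibull and \eqn{\lambda t} for the
#' exponential (identical to Weibull with \eqn{\kappa = 1},
#' \eqn{\sigma = 1/\lambda}).
#'
#' @param family `"weibull"` or `"exponential"`.
#' @param shape Weibull shape \eqn{\kappa > 0} (ignored for exponential).
#' @param scale Weibull scale \eqn{\sigma > 0} in years.
#' @param rate Exponential rate \eqn{\lambda \ge 0} per year (alternative to
#'   `scale` for the exponential family).
#' @param se_shape,se_scale,se_rate Standard errors on the natural scale
#'   (default 0: a deterministic parameter).
#' @param cov_shape_scale Covariance between shape and scale estimates on the
#'   natural scale.
#' @param transition Label, e.g. `"stable_progression"`.
#' @return A `pc_transition_model`.
#' @seealso [fit_transition()], [annual_transition_probability()]
#' @export
#' @examples
#' m <- transition_model("weibull", shape = 1.3, scale = 25,
#'                       transition = "stable_progression")
#' annual_transition_probability(m, 0:5)
transition_model <- function(family = c("weibull", "exponential"),
                             shape = 1, scale = NULL, rate = NULL,
                             se_shape = 0, se_scale = 0, se_rate = NULL,
                             cov_shape_scale = 0,
                             transition = "unnamed") {
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(rate) && is.null(scale)) {
      stop_config("rate", "must be given for an exponential transition")
    }
    if (is.null(rate)) rate <- 1 / scale
    if (rate < 0) stop_config("rate", "must be >= 0")
    if (rate == 0) {
      # zero hazard: infinite scale; degenerate (no uncertainty supported)
      co <- c(log_scale = Inf)
      return(new_transition_model(family, co, NULL, transition))
    }
    scale <- 1 / rate
    if (!is.null(se_rate)) se_scale <- se_rate / rate^2
    v_log <- (se_scale / scale)^2
    co <- c(log_scale = log(scale))
    vc <- matrix(v_log, 1, 1, dimnames = list("log_scale", "log_scale"))
    return(new_transition_model(family, co, vc, transition))
  }
  if (is.null(scale)) stop_config("scale", "must be given for a weibull transition")
  if (shape <= 0) stop_config("shape", "must be > 0")
  if (scale <= 0) stop_config("scale", "must be > 0")
  co <- c(log_scale = log(scale), log_shape = log(shape))
  vc <- matrix(c((se_scale / scale)^2, cov_shape_scale / (scale * shape),
                 cov_shape_scale / (scale * shape), (se_shape / shape)^2),
               2, 2, dimnames = list(names(co), names(co)))
  new_transition_model(family, co, vc, transition)
}

# natural-scale accessors -----------------------------------------------------

tm_shape <- function(model) {
  if (model$family == "exponential") 1 else unname(exp(model$coefficients["log_shape"]))
}

tm_scale <- function(model, arm = NULL) {
  lp <- unname(model$coefficients["log_scale"])
  if (!is.null(arm) && !is.null(model$arm_levels)) {
    arm <- as.character(arm)
    if (!arm %in% model$arm_levels) {
      stop(sprintf("arm '%s' not among fitted levels (%s)", arm,
                   paste(model$arm_levels, collapse = ", ")), call. = FALSE)
    }
    if (arm != model$arm_levels[1]) {
      lp <- lp + unname(model$coefficients[paste0("arm", arm)])
    }
  }
  exp(lp)
}

tm_rate <- function(model, arm = NULL) 1 / tm_scale(model, arm)

#' @export
print.pc_transition_model <- function(x, ...) {
  if (x$family == "exponential") {
    cat(sprintf("<pc_transition_model> %s: exponential, rate %.4g /year\n",
                x$transition, tm_rate(x)))
  } else {
    cat(sprintf("<pc_transition_model> %s: weibull, shape %.4g, scale %.4g years\n",
                x$transition, tm_shape(x), tm_scale(x)))
  }
  if (!is.null(x$arm_levels)) {
    hrs <- vapply(x$arm_levels[-1], function(a) hazard_ratio(x, a), numeric(1))
    cat("  arm hazard ratios vs", x$arm_levels[1], ":",
        paste(sprintf("%s=%.3f", x$arm_levels[-1], hrs), collapse = ", "), "\n")
  }
  if (!is.na(x$loglik)) {
    cat(sprintf("  logLik %.2f, AIC %.2f, %d events / %d subjects\n",
                x$loglik, x$aic, x$n_events, x$n))
  }
  invisible(x)
}

#' Hazard ratio for a strategy arm relative to the reference arm
#'
#' For a proportional-hazards Weibull fitted on the accelerated-failure-time
#' scale, the hazard ratio of arm *a* versus the reference is
#' \eqn{\exp(-\kappa \beta_a)}; for the exponential, \eqn{\exp(-\beta_a)}.
#'
#' @param model A fitted `pc_transition_model` with an arm covariate.
#' @param arm Arm label.
#' @return The hazard ratio (1 for the reference arm).
#' @export
hazard_ratio <- function(model, arm) {
  if (is.null(model$arm_levels)) return(1)
  arm <- as.character(arm)
  if (arm == model$arm_levels[1]) return(1)
  beta <- unname(model$coefficients[paste0("arm", arm)])
  exp(-tm_shape(model) * beta)
}

trial_data_hash <- function(time, event) {
  paste(length(time), sum(event), format(sum(time), digits = 12), sep = ":")
}

#' Fit a parametric transition model to right-censored durations
#'
#' Maximum-likelihood fit of a Weibull or exponential hazard to censored
#' times via [survival::survreg()].  When `arm` is supplied it enters as a
#' proportional-hazards covariate (fitted on the AFT scale and convertible
#' to hazard ratios with [hazard_ratio()]).  The exponential MLE equals
#' (number of events) / (total exposure time).
#'
#' @param time Positive durations in years.
#' @param event Event indicator (1/TRUE observed, 0/FALSE censored).
#' @param family `"weibull"` or `"exponential"`.
#' @param arm Optional factor of strategy labels, reference level first.
#' @param transition Label stored on the model.
#' @return A `pc_transition_model` with estimation-scale coefficients,
#'   covariance matrix, log-likelihood and AIC.
#' @export
#' @examples
#' # exponential MLE closed form: 3 events over 6 person-years -> rate 0.5
#' m <- fit_transition(c(1, 2, 3), c(1, 1, 1), "exponential")
#' 1 / exp(m$coefficients["log_scale"])
fit_transition <- function(time, event,
                           family = c("weibull", "exponential"),
                           arm = NULL, transition = "unnamed") {
  family <- match.arg(family)
  event <- as.integer(as.logical(event))
  if (length(time) != length(event)) {
    stop("time and event must have the same length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all durations must be positive and finite", call. = FALSE)
  }
  nev <- sum(event)
  if (nev == 0) stop("cannot fit transition model: no events", call. = FALSE)
  min_ev <- if (family == "weibull") 2L else 1L
  if (nev < min_ev) {
    stop(sprintf("family '%s' needs at least %d events (got %d)",
                 family, min_ev, nev), call. = FALSE)
  }
  d <- data.frame(time = time, event = event)
  form <- survival::Surv(time, event) ~ 1
  if (!is.null(arm)) {
    arm <- if (is.factor(arm)) droplevels(arm) else factor(arm)
    d$arm <- arm
    if (nlevels(arm) > 1) form <- survival::Surv(time, event) ~ arm
  }
  fit <- survival::survreg(form, data = d, dist = family,
                           control = survival::survreg.control(maxiter = 500))
  if (anyNA(coef(fit)) || anyNA(fit$var)) {
    stop(sprintf("transition fit did not converge after %d iterations",
                 fit$iter), call. = FALSE)
  }
  co <- coef(fit)
  names(co)[names(co) == "(Intercept)"] <- "log_scale"
  vc <- fit$var
  if (family == "weibull") {
    # survreg's last parameter is log(survreg scale) = -log(shape)
    co <- c(co, log_shape = -log(fit$scale))
    j <- diag(length(co)); j[length(co), length(co)] <- -1
    vc <- j %*% vc %*% t(j)
  }
  dimnames(vc) <- list(names(co), names(co))
  arm_levels <- if (!is.null(arm) && nlevels(arm) > 1) levels(arm) else NULL
  new_transition_model(family, co, vc, transition,
                       arm_levels = arm_levels,
                       loglik = fit$loglik[2], n = length(time),
                       n_events = nev,
                       data_hash = trial_data_hash(time, event))
}

#' Select the better-fitting transition family by AIC
#'
#' Given Weibull and exponential fits to the *same* censored data, returns
#' the fit with the lower AIC; on a tie the exponential wins (fewer
#' parameters, and the exponential is nested within the Weibull at
#' \eqn{\kappa = 1}).  Both AICs are recorded on the returned model.
#'
#' @param weibull_fit,exponential_fit Fits from [fit_transition()] on
#'   identical data.
#' @return The selected `pc_transition_model`, with attribute `aic_both`.
#' @export
select_family <- function(weibull_fit, exponential_fit) {
  stopifnot(inherits(weibull_fit, "pc_transition_model"),
            inherits(exponential_fit, "pc_transition_model"))
  if (weibull_fit$family != "weibull" || exponential_fit$family != "exponential") {
    stop("arguments must be a weibull fit and an exponential fit, in that order",
         call. = FALSE)
  }
  if (!identical(weibull_fit$data_hash, exponential_fit$data_hash)) {
    stop("family selection requires both models fitted to identical data",
         call. = FALSE)
  }
  aics <- c(weibull = weibull_fit$aic, exponential = exponential_fit$aic)
  chosen <- if (aics["exponential"] <= aics["weibull"]) exponential_fit else weibull_fit
  attr(chosen, "aic_both") <- aics
  chosen
}

# cumulative hazard H(t) at the given arm (reference arm if NULL)
cumulative_hazard <- function(model, t, arm = NULL) {
  sigma <- tm_scale(model, arm)
  if (!is.finite(sigma)) return(rep(0, length(t)))  # zero-hazard model
  (t / sigma)^tm_shape(model)
}

#' Annual transition probability from a fitted hazard
#'
#' The probability of making the transition during cycle *t* (the year from
#' *t* to *t*+1), conditional on being at risk at *t*:
#' \deqn{p(t) = 1 - \exp\{H(t) - H(t+1)\}}
#' with \eqn{H(t) = (t/\sigma)^\kappa}.  For the exponential this is
#' constant, \eqn{1 - e^{-\lambda}}; for the Weibull it increases with *t*
#' when \eqn{\kappa > 1} and decreases when \eqn{\kappa < 1}.
#'
#' @param model A `pc_transition_model`.
#' @param t Cycle index(es), non-negative whole years since model start.
#' @param arm Optional arm label for models fitted with an arm covariate.
#' @return Transition probabilities in \[0, 1\], one per element of `t`.
#' @export
#' @examples
#' m <- transition_model("exponential", rate = 0.2)
#' annual_transition_probability(m, 0:3)  # constant 1 - exp(-0.2)
annual_transition_probability <- function(model, t, arm = NULL) {
  stopifnot(inherits(model, "pc_transition_model"))
  if (any(t < 0)) stop("cycle index must be >= 0", call. = FALSE)
  dh <- cumulative_hazard(model, t + 1, arm) - cumulative_hazard(model, t, arm)
  p <- 1 - exp(-dh)
  pmin(pmax(p, 0), 1)
}

# parameter-table CSV interface ----------------------------------------------

#' Write and read fitted transition parameters as CSV
#'
#' The CSV mirrors a published supplementary parameter table: one row per
#' transition (and per arm, for models carrying arm-specific hazards), with
#' columns `transition, family, shape, scale_or_rate, se_shape, se_scale,
#' cov_01, subgroup, arm`.  `scale_or_rate` is the Weibull scale in years or
#' the exponential rate per year; standard errors are on the natural scale
#' (delta method).  Reading returns one `pc_transition_model` per row, named
#' `transition` or `transition.arm`; cross-arm estimation correlation is not
#' representable in the flat table and is dropped.
#'
#' @param models A named list of `pc_transition_model` objects.
#' @param path CSV path.
#' @param subgroup Optional subgroup label written to every row.
#' @return `write_transition_csv` returns `path` invisibly;
#'   `read_transition_csv` returns a named list of models.
#' @export
write_transition_csv <- function(models, path, subgroup = NA_character_) {
  if (inherits(models, "pc_transition_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    arms <- if (is.null(m$arm_levels)) NA_character_ else m$arm_levels
    do.call(rbind, lapply(arms, function(a) {
      arm <- if (is.na(a)) NULL else a
      kappa <- tm_shape(m)
      sigma <- tm_scale(m, arm)
      # delta-method natural-scale SEs from the estimation-scale covariance
      v <- m$vcov
      g_ls <- "log_scale"
      v_ls <- v[g_ls, g_ls]
      if (!is.null(arm) && a != m$arm_levels[1]) {
        ca <- paste0("arm", a)
        v_ls <- v[g_ls, g_ls] + v[ca, ca] + 2 * v[g_ls, ca]
      }
      if (m$family == "weibull") {
        se_shape <- kappa * sqrt(max(v["log_shape", "log_shape"], 0))
        se_scale <- sigma * sqrt(max(v_ls, 0))
        cov01 <- kappa * sigma * v[g_ls, "log_shape"]
        data.frame(transition = m$transition, family = "weibull",
                   shape = kappa, scale_or_rate = sigma,
                   se_shape = se_shape, se_scale = se_scale, cov_01 = cov01,
                   subgroup = subgroup, arm = a, stringsAsFactors = FALSE)
      } else {
        lam <- 1 / sigma
        se_rate <- if (is.finite(sigma)) lam * sqrt(max(v_ls, 0)) else 0
        data.frame(transition = m$transition, family = "exponential",
                   shape = 1, scale_or_rate = lam,
                   se_shape = 0, se_scale = se_rate, cov_01 = 0,
                   subgroup = subgroup, arm = a, stringsAsFactors = FALSE)
      }
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("transition", "family", "shape", "scale_or_rate",
            "se_shape", "se_scale", "cov_01")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(df))
  nm <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    out[[i]] <- if (r$family == "weibull") {
      transition_model("weibull", shape = r$shape, scale = r$scale_or_rate,
                       se_shape = r$se_shape, se_scale = r$se_scale,
                       cov_shape_scale = r$cov_01, transition = r$transition)
    } else {
      transition_model("exponential", rate = r$scale_or_rate,
                       se_rate = r$se_scale, transition = r$transition)
    }
    arm <- if ("arm" %in% names(df)) r$arm else NA
    nm[i] <- if (is.na(arm) || !nzchar(arm)) r$transition else {
      paste(r$transition, arm, sep = ".")
    }
  }
  names(out) <- nm
  out
}
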