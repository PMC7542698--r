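test_that("exponential MLE equals events over exposure", {
  m <- fit_transition(c(1, 2, 3), c(1, 1, 1), "exponential")
  expect_equal(unname(1 / exp(m$coefficients["log_scale"])), 0.5,
               tolerance = 1e-8)
  # with censoring: 2 events over 1+2+3+4 = 10 person-years
  m2 <- fit_transition(1:4, c(1, 1, 0, 0), "exponential")
  expect_equal(unname(1 / exp(m2$coefficients["log_scale"])), 0.2,
               tolerance = 1e-8)
})

test_that("weibull fit recovers simulated parameters and nests the exponential", {
  set.seed(101)
  x <- rweibull(10000, shape = 1.3, scale = 25)
  m <- fit_transition(x, rep(1, 10000), "weibull")
  kappa <- exp(m$coefficients[["log_shape"]])
  sigma <- exp(m$coefficients[["log_scale"]])
  expect_gt(kappa, 1.25); expect_lt(kappa, 1.35)
  expect_gt(sigma, 24); expect_lt(sigma, 26)
  # weibull fitted to exponential truth: shape near 1
  y <- rexp(10000, rate = 0.1)
  m2 <- fit_transition(y, rep(1, 10000), "weibull")
  k2 <- exp(m2$coefficients[["log_shape"]])
  expect_gt(k2, 0.95); expect_lt(k2, 1.05)
})

test_that("fit matches an independent parametric survival implementation", {
  skip_if_not_installed("flexsurv")
  set.seed(77)
  x <- rweibull(800, 1.4, 12)
  cens <- pmin(x, 10)
  ev <- as.integer(x <= 10)
  m <- fit_transition(cens, ev, "weibull")
  ref <- flexsurv::flexsurvreg(survival::Surv(cens, ev) ~ 1, dist = "weibull")
  expect_equal(exp(m$coefficients[["log_shape"]]),
               unname(ref$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(exp(m$coefficients[["log_scale"]]),
               unname(ref$res["scale", "est"]), tolerance = 1e-4)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_transition(1:3, c(0, 0, 0), "exponential"), "no events")
  expect_error(fit_transition(1:3, c(1, 0, 0), "weibull"), "at least 2")
  expect_error(fit_transition(c(-1, 2), c(1, 1), "exponential"), "positive")
})

test_that("AIC family selection picks the generating family", {
  set.seed(5)
  w <- rweibull(5000, shape = 2, scale = 10)
  ev <- rep(1, 5000)
  sel <- select_family(fit_transition(w, ev, "weibull"),
                       fit_transition(w, ev, "exponential"))
  expect_identical(sel$family, "weibull")
  # under an exponential truth the Weibull wins only when the likelihood
  # ratio beats the AIC penalty, asymptotically P(chisq_1 > 2) ~ 0.157 of
  # the time; check the empirical selection rate is consistent with that
  picks <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    x <- rexp(5000, 0.2)
    select_family(fit_transition(x, rep(1, 5000), "weibull"),
                  fit_transition(x, rep(1, 5000), "exponential"))$family
  }, character(1))
  expect_gte(mean(picks == "exponential"), 0.70)
})

test_that("family selection ties break to the exponential and data must match", {
  set.seed(6)
  x <- rexp(2000, 0.3)
  wf <- fit_transition(x, rep(1, 2000), "weibull")
  ef <- fit_transition(x, rep(1, 2000), "exponential")
  # near-identical log-likelihoods: the AIC penalty decides for exponential
  sel <- select_family(wf, ef)
  if (ef$aic <= wf$aic) expect_identical(sel$family, "exponential")
  other <- fit_transition(x[-1], rep(1, 1999), "exponential")
  expect_error(select_family(wf, other), "identical data")
})

test_that("annual transition probability follows the cumulative-hazard form", {
  m0 <- transition_model("exponential", rate = 0)
  expect_equal(annual_transition_probability(m0, 0:50), rep(0, 51))
  m <- transition_model("exponential", rate = 0.2)
  expect_equal(annual_transition_probability(m, 0:10),
               rep(1 - exp(-0.2), 11), tolerance = 1e-12)
  # weibull with shape 1, scale 5 reduces to exponential rate 0.2
  w1 <- transition_model("weibull", shape = 1, scale = 5)
  expect_equal(annual_transition_probability(w1, c(0, 7)),
               rep(1 - exp(-0.2), 2), tolerance = 1e-12)
  expect_error(annual_transition_probability(m, -1), ">= 0")
})

test_that("weibull with shape 1 is the exponential for all cycles", {
  for (lam in c(0.05, 0.2, 0.7)) {
    w <- transition_model("weibull", shape = 1, scale = 1 / lam)
    e <- transition_model("exponential", rate = lam)
    expect_equal(annual_transition_probability(w, 0:50),
                 annual_transition_probability(e, 0:50), tolerance = 1e-10)
  }
})

test_that("p(t) is monotone in t according to the shape parameter", {
  up <- annual_transition_probability(
    transition_model("weibull", shape = 1.6, scale = 20), 0:50)
  down <- annual_transition_probability(
    transition_model("weibull", shape = 0.7, scale = 20), 0:50)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down[-1]) < 0))  # t = 0 excluded: p(0) uses H(0) = 0
  expect_true(down[1] > down[2])
})

test_that("arm covariate produces proportional hazards with recoverable HR", {
  set.seed(42)
  n <- 4000
  arm <- factor(rep(c("AM", "RP"), each = n), levels = c("AM", "RP"))
  hr <- ifelse(arm == "RP", 0.5, 1)
  x <- rweibull(2 * n, shape = 1.3, scale = 25 * hr^(-1 / 1.3))
  m <- fit_transition(x, rep(1, 2 * n), "weibull", arm = arm)
  expect_equal(hazard_ratio(m, "RP"), 0.5, tolerance = 0.05)
  expect_identical(hazard_ratio(m, "AM"), 1)
  # arm-specific annual probabilities differ accordingly
  p_am <- annual_transition_probability(m, 5, arm = "AM")
  p_rp <- annual_transition_probability(m, 5, arm = "RP")
  expect_lt(p_rp, p_am)
})

test_that("transition parameter CSV round-trips fits", {
  set.seed(9)
  x <- rweibull(2000, 1.3, 25)
  cens <- pmin(x, 12)
  m <- fit_transition(cens, as.integer(x <= 12), "weibull",
                      transition = "stable_progression")
  e <- fit_transition(rexp(2000, 0.25), rep(1, 2000), "exponential",
                      transition = "metastatic_death")
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(list(m, e), path)
  back <- read_transition_csv(path)
  expect_named(back, c("stable_progression", "metastatic_death"))
  expect_equal(annual_transition_probability(back$stable_progression, 0:30),
               annual_transition_probability(m, 0:30), tolerance = 1e-6)
  expect_equal(annual_transition_probability(back$metastatic_death, 0:30),
               annual_transition_probability(e, 0:30), tolerance = 1e-6)
})
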