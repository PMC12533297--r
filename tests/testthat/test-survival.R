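test_that("Kaplan-Meier matches closed forms on tiny fixtures", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cens$surv == 1))

  # subject censored at an event time stays in the risk set there
  tie <- km_estimate(c(1, 1), c(1, 0))
  expect_equal(tie$n_risk, 2)
  expect_equal(tie$surv, 0.5)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no censoring is the empirical survival function", {
  for (seed in 1:5) {
    tm <- lnmts:::.with_seed(seed, stats::rexp(40, 0.01))
    km <- km_estimate(tm, rep(1, 40))
    ecdf_surv <- vapply(km$time, function(u) mean(tm > u), numeric(1))
    expect_equal(km$surv, ecdf_surv)
  }
})

test_that("KM approaches the analytic exponential survival curve", {
  lambda <- 1 / 500
  tm <- lnmts:::.with_seed(42, stats::rexp(200, lambda))
  km <- km_estimate(tm, rep(1, 200))
  t_med <- log(2) / lambda
  s_hat <- km_survival_at(km, t_med)
  se_mc <- sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(s_hat - exp(-lambda * t_med)), 3 * se_mc)
})

test_that("survival at a time beyond follow-up is 'not reached', not extrapolated", {
  km <- km_estimate(c(100, 200, 300), c(1, 0, 1))
  expect_true(is.na(km_survival_at(km, 400)))
  expect_true(attr(km_survival_at(km, 400), "not_reached"))
  expect_equal(km_survival_at(km, 50), 1)
})

test_that("log-rank is zero for identical groups and matches the 2x2 closed form", {
  tm <- c(3, 6, 9, 12); ev <- c(1, 1, 0, 1)
  same <- logrank_test(c(tm, tm), c(ev, ev), rep(1:2, each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  # single pooled event time: O-E = 1 - 2/4 = 0.5,
  # V = d(n-d)/(n-1) * nA*nB/n^2 = 1*3/3 * 4/16 = 0.25, chi2 = 1
  lr <- logrank_test(times = c(1, 2, 1, 3), events = c(1, 0, 0, 0),
                     group = c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 1, tolerance = 1e-12)
  expect_equal(lr$df, 1L)

  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), "2 groups")
  expect_error(
    logrank_test(1:4, rep(1, 4), factor(c(1, 1, 2, 2), levels = 1:3)),
    "zero subjects")
})

test_that("log-rank is invariant to label permutation and time shifts", {
  coh <- simulate_cohort(c(LRS = 40, MRS = 40, HRS = 40), seed = 17)
  base <- logrank_test(coh$os_time, coh$os_event, coh$subtype_true)
  relab <- logrank_test(coh$os_time, coh$os_event,
                        factor(coh$subtype_true,
                               levels = c("HRS", "LRS", "MRS")))
  expect_equal(relab$statistic, base$statistic, tolerance = 1e-9)
  shift <- logrank_test(coh$os_time + 1000, coh$os_event, coh$subtype_true)
  expect_equal(shift$statistic, base$statistic, tolerance = 1e-12)
})

test_that("log-rank agrees with the reference implementation", {
  skip_if_not_installed("survival")
  coh <- simulate_cohort(c(LRS = 50, MRS = 50, HRS = 50), seed = 23)
  mine <- logrank_test(coh$os_time, coh$os_event, coh$subtype_true)
  ref <- survival::survdiff(
    survival::Surv(coh$os_time, coh$os_event) ~ coh$subtype_true)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
})

test_that("Cox fit agrees with the reference implementation on a tied fixture", {
  skip_if_not_installed("survival")
  fx <- survival_fixture_50()
  for (ties in c("breslow", "efron")) {
    mine <- cox_fit(fx$time, fx$event, fx[, c("x1", "x2")], ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                           data = fx, ties = ties)
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(mine$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-6)
  }
})

test_that("Cox input validation and separation handling", {
  fx <- survival_fixture_50()
  expect_error(cox_fit(fx$time, fx$event, cbind(z = rep(0, 50))),
               "constant")
  expect_error(cox_fit(fx$time, fx$event,
                       matrix(stats::rnorm(50 * 50), 50)), "more subjects")
  # perfectly separating covariate: flagged, not silent
  tm <- c(1:10, 101:110); ev <- rep(1, 20)
  x <- cbind(sep = rep(c(1, 0), each = 10))
  expect_warning(fit <- cox_fit(tm, ev, x), "monotone likelihood|converge")
  expect_identical(fit$flag, "monotone_likelihood")
})

test_that("Cox coefficient converges to the true log hazard ratio", {
  coh <- simulate_cohort(c(LRS = 2500, MRS = 0, HRS = 2500),
                         hazard_ratios = c(MRS = 1, HRS = 2),
                         censoring_rate = 0.1, horizon = 1e6, seed = 55)
  fit <- cox_fit(coh$os_time, coh$os_event,
                 cbind(hrs = as.numeric(coh$subtype_true == "HRS")))
  expect_lt(abs(fit$coefficients[["hrs"]] - log(2)), 0.05)
  expect_true(fit$converged)
  expect_true(fit$ci_lower[1] < fit$hr[1] && fit$hr[1] < fit$ci_upper[1])
})
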