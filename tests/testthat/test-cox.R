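test_that("log partial likelihood matches hand-computed values", {
  # beta = 0, no ties: -sum(log |R_i|)
  expect_equal(efron_loglik(0, toy_a, "x"), -log(3) - log(2))
  # two deaths tied at t=1 among three subjects, beta = 0:
  # Efron denominators 3 and 3 - (1/2)*2, so -log(3) - log(2)
  tied <- data.frame(time = c(1, 1, 2), event = c(1, 1, 0), x = c(1, 0, 1))
  expect_equal(efron_loglik(0, tied, "x"), -log(3) - log(2))
  # with no covariates the value is the same whatever "beta" is
  expect_equal(efron_loglik(numeric(0), toy_a, character(0)),
               efron_loglik(numeric(0), toy_a, character(0)))
  expect_error(efron_loglik(Inf, toy_a, "x"), "non-finite")
})

test_that("the toy dataset has the analytic solution -log(2)/2", {
  f <- cox_efron(Surv(time, event) ~ x, toy_a)
  expect_equal(unname(coef(f)), -log(2) / 2, tolerance = 1e-9)
  expect_true(f$converged)
  expect_gte(f$loglik, f$loglik_null)
})

test_that("fitting rejects covariates without variation", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(2, 2, 2))
  expect_error(cox_efron(Surv(time, event) ~ x, d), "no variation")
})

test_that("separation is reported as non-convergence, not a crash", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 0, 0, 0),
                  x = c(1, 1, 1, 0, 0, 0))
  f <- cox_efron(Surv(time, event) ~ x, d)
  expect_false(f$converged)
  expect_match(f$flag, "separation")
})

test_that("estimates are invariant to covariate location and scale", {
  d <- rand_surv(40, p = 1, seed = 3)
  f0 <- cox_efron(Surv(time, event) ~ x1, d)
  d$xs <- d$x1 + 100
  fs <- cox_efron(Surv(time, event) ~ xs, d)
  expect_equal(unname(coef(fs)), unname(coef(f0)), tolerance = 1e-7)
  d$xc <- d$x1 * 4
  fc <- cox_efron(Surv(time, event) ~ xc, d)
  expect_equal(unname(coef(fc)) * 4, unname(coef(f0)), tolerance = 1e-7)
})

test_that("coefficients and covariance match the reference implementation", {
  for (seed in 1:25) {
    d <- rand_surv(sample(10:30, 1), p = 2, seed = 600 + seed)
    f1 <- cox_efron(Surv(time, event) ~ x1 + x2, d)
    f2 <- survival::coxph(Surv(time, event) ~ x1 + x2, d, ties = "efron")
    expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-6)
    expect_equal(unname(f1$var), unname(f2$var), tolerance = 1e-5)
    expect_equal(f1$loglik, f2$loglik[2], tolerance = 1e-8)
  }
})

test_that("simulated cohort recovers the true hazard ratio", {
  d <- sim_ph(1000, seed = 77, beta1 = 0.7)
  f <- cox_efron(Surv(time, event) ~ x1 + x2, d)
  se <- sqrt(diag(f$var))[1L]
  expect_lt(abs(coef(f)[["x1"]] - 0.7), 3 * se)
})

test_that("Breslow baseline hazard follows the closed forms", {
  # no covariates on the AB-recipient records: single increment 1/9 at 616
  ab <- read_cohort(ab_path)
  f0 <- cox_efron(Surv(time, event) ~ 1, ab)
  bh <- baseline_hazard(f0)
  expect_equal(bh$time, 616)
  expect_equal(bh$hazard, 1 / 9)
  # beta = 0 (no covariates) equals Nelson-Aalen increments d_i / |R_i|
  d <- rand_surv(25, p = 1, seed = 9)
  rs <- build_risk_structure(d)
  na_inc <- rs$d / lengths(rs$risk_sets)
  fnull <- cox_efron(Surv(time, event) ~ 1, d)
  expect_equal(baseline_hazard(fnull)$hazard, unname(na_inc))
  # predicted survival is 1 before the first event
  f <- cox_efron(Surv(time, event) ~ x1, d)
  S <- predict(f, times = min(d$time[d$event == 1]) / 2)
  expect_true(all(S == 1))
  # survival predictions are nonincreasing in time
  tt <- sort(unique(d$time[d$event == 1]))
  Sm <- predict(f, times = tt)
  expect_true(all(diff(t(Sm)[, 1]) <= 1e-12))
})
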