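test_that("knots are placed at failure-time quantiles", {
  d <- data.frame(time = 1:20, event = rep(1, 20))
  kn <- place_knots(d, K = 4)
  expect_equal(kn$K, 4L)
  expect_equal(kn$tau, c(0, 6, 11, 16, 20))
  # five events per left-closed interval
  counts <- table(cut(d$time, kn$tau, right = FALSE,
                      include.lowest = FALSE))
  expect_equal(unname(c(counts)) + c(0, 0, 0, 1), rep(5, 4))  # t=20 closed
  expect_equal(place_knots(d, K = 1)$tau, c(0, 20))
  # ties cannot be split: more intervals than distinct times fails,
  # coincident quantile knots collapse with a warning
  dt <- data.frame(time = rep(5, 10), event = rep(1, 10))
  expect_error(place_knots(dt, K = 2), "distinct event times")
  dh <- data.frame(time = c(1, rep(5, 8), 9), event = rep(1, 10))
  expect_warning(k2 <- place_knots(dh, K = 3), "collapsed")
  expect_lt(k2$K, 3L)
  expect_error(place_knots(d, K = 25), "distinct event times")
})

test_that("the first-difference penalty follows its closed form", {
  expect_equal(penalty_value(c(3, 3, 3), 10), 0)
  expect_equal(penalty_value(c(0, 1), 2), 1)
  expect_equal(penalty_value(rnorm(5), 0), 0)
  expect_equal(penalty_value(c(1), 5), 0)            # K = 1
  expect_error(penalty_value(c(0, 1), -1), "nonnegative")
})

test_that("K = 1 reproduces the Cox fit exactly", {
  f0 <- pctvc(Surv(time, event) ~ tv(x), toy_a,
              knots = knot_set(numeric(0), 2))
  fc <- cox_efron(Surv(time, event) ~ x, toy_a)
  expect_identical(unname(coef(f0)), unname(coef(fc)))
  expect_identical(f0$loglik, fc$loglik)
  expect_equal(unname(coef(f0)), -log(2) / 2, tolerance = 1e-9)
  # curve is flat and equals the Cox estimate and CI
  cc <- coefficient_curve(f0, "x")
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$estimate, unname(coef(fc)))
  expect_equal(c(cc$lower, cc$upper),
               unname(confint(fc)[1, ]), tolerance = 1e-9)
})

test_that("penalized loglik equals the Efron loglik minus the penalty", {
  d <- rand_surv(30, p = 1, seed = 21)
  kn <- place_knots(d, K = 2)
  f <- pctvc(Surv(time, event) ~ tv(x1), d, knots = kn, lambda = 1.5)
  a <- unname(f$alpha$x1)
  # independent brute-force evaluation over risk sets
  expect_equal(penalized_loglik(f),
               brute_pll_k2(a, d$time, d$event, d$x1, kn$tau[2],
                            lambda = 1.5),
               tolerance = 1e-10)
  # all-zero coefficients: penalty vanishes
  th0 <- f$coefficients * 0
  expect_equal(penalized_loglik(f, th0),
               brute_pll_k2(c(0, 0), d$time, d$event, d$x1, kn$tau[2]),
               tolerance = 1e-12)
})

test_that("infinite smoothing collapses to the proportional-hazards fit", {
  for (seed in c(5, 23)) {
    d <- rand_surv(60, p = 2, seed = seed)
    fc <- cox_efron(Surv(time, event) ~ x1 + x2, d)
    fg <- pctvc(Surv(time, event) ~ tv(x1) + tv(x2), d, K = 3,
                lambda = 1e8)
    for (nm in c("x1", "x2")) {
      expect_lt(max(abs(fg$alpha[[nm]] - coef(fc)[[nm]])), 1e-3)
    }
    expect_lt(abs(fg$loglik - fc$loglik), 1e-3)
  }
})

test_that("zero smoothing equals the interval-interaction Cox fit", {
  d <- sim_ph(150, seed = 12)
  kn <- place_knots(d, K = 3)
  f <- pctvc(Surv(time, event) ~ tv(x1), d, knots = kn, lambda = 0)
  # counting-process oracle; cuts just below the knots realise the
  # left-closed coefficient intervals (knots sit at failure times)
  ep <- survival::survSplit(Surv(time, event) ~ x1, data = as.data.frame(d),
                            cut = kn$tau[2:3] - 1e-7, episode = "iv")
  fo <- survival::coxph(Surv(tstart, time, event) ~ factor(iv):x1, ep,
                        ties = "efron",
                        control = survival::coxph.control(timefix = FALSE))
  expect_equal(unname(f$alpha$x1), unname(coef(fo)), tolerance = 1e-6)
  expect_equal(f$loglik, fo$loglik[2], tolerance = 1e-8)
})

test_that("episode likelihood equals direct evaluation for off-grid knots", {
  d <- rand_surv(50, p = 1, seed = 31)
  mids <- stats::quantile(d$time[d$event == 1], c(1 / 3, 2 / 3)) + 0.005
  kn <- knot_set(unname(mids), max(d$time[d$event == 1]))
  f <- pctvc(Surv(time, event) ~ tv(x1), d, knots = kn, lambda = 0)
  ep <- survival::survSplit(Surv(time, event) ~ x1, data = d,
                            cut = kn$tau[2:3], episode = "iv")
  fo <- survival::coxph(Surv(tstart, time, event) ~ factor(iv):x1, ep,
                        ties = "efron")
  expect_equal(f$loglik, fo$loglik[2], tolerance = 1e-9)
})

test_that("effective df moves monotonically from K to 1 with lambda", {
  d <- sim_ph(200, seed = 4)
  kn <- place_knots(d, K = 4)
  lams <- c(0, 1, 10, 100, 1e4, 1e8)
  dfs <- vapply(lams, function(l) {
    f <- pctvc(Surv(time, event) ~ tv(x1), d, knots = kn, lambda = l)
    unname(f$edf["x1"])
  }, 0)
  expect_equal(dfs[1], 4, tolerance = 1e-8)
  expect_lt(abs(dfs[length(dfs)] - 1), 0.05)
  expect_true(all(diff(dfs) < 1e-8))
})

test_that("the df search hits its target", {
  d <- sim_ph(250, seed = 8)
  f <- pctvc(Surv(time, event) ~ tv(x1) + tv(x2), d, df = 3, K = 6)
  expect_lt(abs(f$edf[["x1"]] - 3), 0.011)
  expect_lt(abs(f$edf[["x2"]] - 3), 0.011)
  expect_true(all(f$lambda > 0))
  # requesting df above K caps with a warning
  expect_warning(f2 <- pctvc(Surv(time, event) ~ tv(x1), d, df = 4, K = 2),
                 "capped")
  expect_equal(unname(f2$edf["x1"]), 2, tolerance = 1e-8)
})

test_that("a factor block shares one lambda across its indicators", {
  set.seed(19)
  d <- as.data.frame(sim_ph(300, seed = 19))
  d$bt <- factor(sample(c("O", "A", "B"), nrow(d), TRUE, c(.5, .3, .2)),
                 levels = c("O", "A", "B"))
  f <- pctvc(Surv(time, event) ~ tv(bt), d, df = 2, K = 4)
  expect_length(f$lambda, 1L)
  expect_named(f$alpha, c("btA", "btB"))
  # block trace target: 2 per indicator
  expect_lt(abs(sum(f$edf) - 4), 0.05)
})

test_that("mixed fits keep time-invariant terms flat", {
  d <- sim_ph(200, seed = 14)
  f <- pctvc(Surv(time, event) ~ tv(x1) + x2, d, df = 2, K = 4)
  expect_named(f$gamma, "x2")
  cc <- coefficient_curve(f, "x2")
  expect_equal(nrow(cc), 1L)
  ov <- test_overall(f, "x2")
  expect_equal(ov$df, 1)
  expect_error(test_proportionality(f, "x2"), "tv")
})

test_that("proportionality test is undefined for a single interval", {
  f <- pctvc(Surv(time, event) ~ tv(x), toy_a,
              knots = knot_set(numeric(0), 2))
  expect_error(test_proportionality(f, "x"), "K = 1")
})

test_that("a step effect is detected and recovered in direction", {
  d <- sim_switch(1000, seed = 41)
  f <- pctvc(Surv(time, event) ~ tv(x1), d, df = 4)
  expect_lt(test_proportionality(f, "x1")$p.value, 0.01)
  expect_lt(test_overall(f, "x1")$p.value, 0.001)
  # fitted levels trend downward (true effect switches +1 -> -1)
  cc <- coefficient_curve(f, "x1")
  expect_lt(cor(seq_len(nrow(cc)), cc$estimate, method = "spearman"), 0)
  expect_gt(cc$estimate[1], cc$estimate[nrow(cc)])
  # band contains the point estimate
  expect_true(all(cc$lower <= cc$estimate & cc$estimate <= cc$upper))
})

test_that("model-based survival predictions behave like survival curves", {
  d <- sim_ph(150, seed = 9)
  f <- pctvc(Surv(time, event) ~ tv(x1), d, df = 2, K = 3)
  tgrid <- seq(50, max(f$knots$tau) - 1, length.out = 12)
  S <- predict(f, newdata = data.frame(x1 = c(-1, 0, 1)), times = tgrid)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-12))))
  # baseline: x = 0 matches the cumulative baseline hazard
  bh <- baseline_hazard(f)
  S0 <- predict(f, newdata = data.frame(x1 = 0), times = bh$time)
  expect_equal(unname(drop(S0)), bh$surv, tolerance = 1e-12)
  # before the first event the survival is 1
  expect_equal(unname(drop(predict(f, newdata = data.frame(x1 = 2),
                                   times = bh$time[1] / 2))), 1)
  # K = 1 predictions equal the Cox predictions exactly
  f1 <- pctvc(Surv(time, event) ~ tv(x1), d,
              knots = knot_set(numeric(0), max(d$time[d$event == 1])))
  fc <- cox_efron(Surv(time, event) ~ x1, d)
  expect_equal(predict(f1, times = tgrid[1:5]),
               predict(fc, times = tgrid[1:5]), tolerance = 1e-12)
  # extrapolation beyond the last knot is flagged
  expect_warning(predict(f, newdata = data.frame(x1 = 0),
                         times = max(f$knots$tau) + 100),
                 "extrapolation")
})

test_that("unseen factor levels at prediction time fail with the level named", {
  d <- as.data.frame(sim_ph(120, seed = 25))
  d$g <- factor(sample(c("a", "b"), nrow(d), TRUE))
  f <- pctvc(Surv(time, event) ~ tv(g), d, df = 2, K = 3)
  expect_error(predict(f, newdata = data.frame(g = "zzz"), times = 100),
               "zzz")
})
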