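sim_candidates <- function(n, seed, beta1 = 1) {
  sc <- cohort_scenario(
    n = n, baseline = list(cuts = numeric(0), rates = 0.002),
    covariates = list(
      x1 = list(type = "normal", mean = 0, sd = 1),
      n1 = list(type = "normal", mean = 0, sd = 1),
      n2 = list(type = "binary", p = 0.4),
      n3 = list(type = "normal", mean = 0, sd = 2),
      n4 = list(type = "binary", p = 0.2)),
    effects = list(x1 = beta1),
    censoring = c(100, 900))
  simulate_cohort(sc, seed = seed)
}

test_that("the univariable screen keeps a true effect among nulls", {
  d <- sim_candidates(300, seed = 51)
  scr <- univariable_screen(d, c("x1", "n1", "n2", "n3", "n4"),
                            alpha = 0.15, df = 4)
  expect_true("x1" %in% scr$passed)
  expect_equal(nrow(scr$trace), 5L)
  expect_true(all(scr$trace$decision[scr$trace$candidate == "x1"] == "pass"))
  # deterministic: same data gives an identical trace
  scr2 <- univariable_screen(d, c("x1", "n1", "n2", "n3", "n4"),
                             alpha = 0.15, df = 4)
  expect_identical(scr$trace, scr2$trace)
})

test_that("screening an empty candidate list returns an empty result", {
  d <- sim_candidates(100, seed = 52)
  scr <- univariable_screen(d, character(0))
  expect_length(scr$passed, 0L)
})

test_that("forward selection enters a dominant effect first and stops", {
  d <- sim_candidates(300, seed = 53)
  fwd <- forward_select(d, c("n1", "x1", "n2"), entry_alpha = 0.05, df = 4)
  expect_equal(fwd$selected[1L], "x1")
  expect_s3_class(fwd$fit, "gray_pctvc")
  # every entered block was at or below the entry threshold at entry time
  entered <- fwd$trace[fwd$trace$decision == "enter", ]
  expect_true(all(entered$p <= 0.05))
})

test_that("all-null candidates select nothing", {
  d <- sim_candidates(250, seed = 540, beta1 = 0)
  fwd <- forward_select(d, c("n1", "n2", "n3"), entry_alpha = 0.05, df = 4)
  expect_length(fwd$selected, 0L)
  expect_null(fwd$fit)
})

test_that("only one of two strongly correlated effects enters", {
  set.seed(55)
  n <- 300
  z <- rnorm(n)
  x1 <- z + rnorm(n, sd = sqrt(1 / 0.9^2 - 1) * 0)  # build rho = 0.9 pair
  x1 <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  x2 <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  rate <- 0.002 * exp(0.8 * z)
  tev <- rexp(n) / rate
  cens <- runif(n, 100, 900)
  d <- data.frame(time = pmin(tev, cens), event = as.integer(tev <= cens),
                  x1 = x1, x2 = x2)
  fwd <- forward_select(d, c("x1", "x2"), entry_alpha = 0.05, df = 4)
  expect_equal(length(fwd$selected), 1L)
})

test_that("interaction checks flag a real product effect and skip trivia", {
  set.seed(56)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  rate <- 0.002 * exp(0.3 * x1 + 0.3 * x2 + 1.2 * x1 * x2)
  tev <- rexp(n) / rate
  cens <- runif(n, 100, 900)
  d <- data.frame(time = pmin(tev, cens), event = as.integer(tev <= cens),
                  x1 = x1, x2 = x2)
  f <- pctvc(Surv(time, event) ~ tv(x1) + tv(x2), d, df = 2, K = 3)
  rep1 <- interaction_check(f, d)
  expect_equal(nrow(rep1), 1L)            # one unordered pair, once
  expect_true(rep1$flagged)
  # single-covariate model: nothing to check
  f1 <- pctvc(Surv(time, event) ~ tv(x1), d, df = 2, K = 3)
  expect_equal(nrow(interaction_check(f1, d)), 0L)
})

test_that("the null pass rate of the screen is near its nominal level", {
  reps <- 400
  pass <- logical(reps)
  for (r in seq_len(reps)) {
    sc <- cohort_scenario(
      n = 150, baseline = list(cuts = numeric(0), rates = 0.002),
      covariates = list(xnull = list(type = "normal", mean = 0, sd = 1)),
      effects = list(), censoring = c(100, 900))
    d <- simulate_cohort(sc, seed = 40000 + r)
    scr <- univariable_screen(d, "xnull", alpha = 0.15, df = 4)
    pass[r] <- "xnull" %in% scr$passed
  }
  expect_gte(mean(pass), 0.10)
  expect_lte(mean(pass), 0.20)
})
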