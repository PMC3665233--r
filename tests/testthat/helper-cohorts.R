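# Shared fixtures built in code.

library(survival)

ab_path <- system.file("extdata", "ab_recipients.csv", package = "graytvc")

# toy three-subject dataset with the analytic Cox solution -log(2)/2
toy_a <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 0, 1))

# proportional-hazards cohort: x1 normal with constant effect, x2 null binary
sim_ph <- function(n, seed, beta1 = 0.7, censoring = c(100, 900)) {
  sc <- cohort_scenario(
    n = n, baseline = list(cuts = numeric(0), rates = 0.002),
    covariates = list(x1 = list(type = "normal", mean = 0, sd = 1),
                      x2 = list(type = "binary", p = 0.5)),
    effects = if (beta1 != 0) list(x1 = beta1) else list(),
    censoring = censoring)
  simulate_cohort(sc, seed = seed)
}

# cohort with a sign-switching effect on x1 (nonproportional hazards)
sim_switch <- function(n, seed, cut = 300, levels = c(1, -1)) {
  sc <- cohort_scenario(
    n = n, baseline = list(cuts = numeric(0), rates = 0.002),
    covariates = list(x1 = list(type = "normal", mean = 0, sd = 1)),
    effects = list(x1 = list(cuts = cut, levels = levels)),
    censoring = c(100, 900))
  simulate_cohort(sc, seed = seed)
}

# small random right-censored dataset with continuous times (no ties)
rand_surv <- function(n, p = 2, seed) {
  set.seed(seed)
  d <- data.frame(time = rexp(n, 0.1) + 0.01, event = rbinom(n, 1, 0.7))
  for (j in seq_len(p)) d[[paste0("x", j)]] <- rnorm(n)
  if (sum(d$event) < 2) d$event[1:2] <- 1L
  d
}

# independent brute-force evaluation of the (penalized) log partial
# likelihood for one covariate with a K=2 step coefficient: direct sums
# over risk sets, assuming no tied event times.
brute_pll_k2 <- function(a, time, event, x, knot, lambda = 0) {
  ll <- 0
  for (t in sort(time[event == 1])) {
    b <- if (t < knot) a[1] else a[2]
    risk <- which(time >= t)
    i <- which(time == t & event == 1)
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll - lambda / 2 * (a[2] - a[1])^2
}

# independent Breslow log partial likelihood (valid oracle with no ties)
breslow_ll <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(time[event == 1])) {
    risk <- which(time >= t)
    i <- which(time == t & event == 1)
    ll <- ll + sum(eta[i]) - length(i) * log(sum(exp(eta[risk])))
  }
  ll
}
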