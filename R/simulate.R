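# Synthetic right-censored cohorts with piecewise-constant baseline
# hazard and piecewise-constant time-varying covariate effects, sampled
# by exact closed-form inversion of the piecewise-linear cumulative
# hazard.

#' Define a synthetic cohort scenario
#'
#' A scenario fixes the cohort size, a piecewise-constant baseline hazard,
#' covariate distributions, per-covariate effect step functions
#' `beta_j(t)`, and an administrative censoring window.  Given a covariate
#' vector, the hazard `h(t) = h0(t) exp(beta(t)' x)` is piecewise constant
#' on the union of the baseline and effect cut points, so its cumulative
#' hazard is piecewise linear and event times are drawn by exact
#' inversion.
#'
#' @param n number of subjects.
#' @param baseline list with `cuts` (days, possibly empty) and `rates`
#'   (per day, length `length(cuts) + 1`).
#' @param covariates named list of covariate specs, each one of
#'   `list(type = "binary", p = )`,
#'   `list(type = "normal", mean = , sd = )`,
#'   `list(type = "lognormal", meanlog = , sdlog = )`, or
#'   `list(type = "categorical", levels = , probs = )` (first level is the
#'   reference).
#' @param effects named list: for a numeric or binary covariate either a
#'   single log hazard ratio or `list(cuts = , levels = )`; for a
#'   categorical covariate a named list of such entries per non-reference
#'   level.  Unlisted covariates/levels have no effect.
#' @param censoring administrative censoring window `c(lo, hi)` in days
#'   (uniform), or `NULL` for no censoring.
#' @return Object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n, baseline = list(cuts = numeric(0), rates = 0.001),
                            covariates = list(), effects = list(),
                            censoring = NULL) {
  stopifnot(n >= 1, length(baseline$rates) == length(baseline$cuts) + 1L,
            all(baseline$rates > 0))
  if (length(baseline$cuts) && any(diff(c(0, baseline$cuts)) <= 0)) {
    stop("baseline cuts must be increasing and positive")
  }
  chk_eff <- function(e) {
    if (is.numeric(e) && length(e) == 1L) return(invisible())
    stopifnot(is.list(e), length(e$levels) == length(e$cuts) + 1L)
    if (length(e$cuts) && any(diff(c(0, e$cuts)) <= 0)) {
      stop("effect cuts must be increasing and positive")
    }
  }
  for (nm in names(effects)) {
    e <- effects[[nm]]
    spec <- covariates[[nm]]
    if (!is.null(spec) && identical(spec$type, "categorical") &&
        !is.numeric(e)) {
      lapply(e, chk_eff)
    } else chk_eff(e)
  }
  if (!is.null(censoring)) stopifnot(length(censoring) == 2L,
                                     censoring[1] < censoring[2],
                                     censoring[1] > 0)
  structure(list(n = n, baseline = baseline, covariates = covariates,
                 effects = effects, censoring = censoring),
            class = "cohort_scenario")
}

# stable small string hash for per-covariate random substreams
str_seed <- function(seed, name) {
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 1000003
  as.integer((seed + h * 7919) %% .Machine$integer.max)
}

#' Generate a synthetic right-censored cohort
#'
#' Draws covariates, then event times by closed-form inversion of the
#' subject-specific piecewise-linear cumulative hazard, then an
#' independent uniform administrative censoring time; follow-up time is
#' the minimum with the corresponding event indicator.  Each covariate
#' and each stage uses its own random substream derived from `seed`, so
#' adding a covariate to a scenario does not perturb the other draws.
#'
#' @param scenario a [cohort_scenario()].
#' @param seed integer seed.
#' @return A `survcohort` with attribute `latent` (data frame of the
#'   uncensored event and censoring times).
#' @export
simulate_cohort <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n <- scenario$n
  covs <- list()
  for (nm in names(scenario$covariates)) {
    spec <- scenario$covariates[[nm]]
    set.seed(str_seed(seed, paste0("cov:", nm)))
    covs[[nm]] <- switch(spec$type,
      binary = stats::rbinom(n, 1L, spec$p),
      normal = stats::rnorm(n, spec$mean, spec$sd),
      lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
      categorical = factor(sample(spec$levels, n, TRUE, spec$probs),
                           levels = spec$levels),
      stop("unknown covariate type: ", spec$type))
  }
  ## numeric effect design: one column per (covariate or factor level)
  eff_cols <- list()     # name -> list(x = numeric vec, cuts, levels)
  for (nm in names(scenario$effects)) {
    e <- scenario$effects[[nm]]
    x <- covs[[nm]]
    if (is.null(x)) stop("effect for unknown covariate: ", nm)
    as_step <- function(e) {
      if (is.numeric(e) && length(e) == 1L) {
        list(cuts = numeric(0), levels = e)
      } else list(cuts = e$cuts, levels = e$levels)
    }
    if (is.factor(x) && !is.numeric(e)) {
      for (lv in names(e)) {
        eff_cols[[paste0(nm, ".", lv)]] <-
          c(list(x = as.numeric(x == lv)), as_step(e[[lv]]))
      }
    } else {
      eff_cols[[nm]] <- c(list(x = as.numeric(x)), as_step(e))
    }
  }
  bounds <- sort(unique(c(scenario$baseline$cuts,
                          unlist(lapply(eff_cols, `[[`, "cuts")))))
  b <- c(0, bounds)                     # segment starts; last extends to Inf
  M <- length(b)
  h0 <- scenario$baseline$rates[
    findInterval(b, c(0, scenario$baseline$cuts), rightmost.closed = FALSE)]
  ## per-subject rate in each segment
  lp <- matrix(0, n, M)
  for (ec in eff_cols) {
    lev <- ec$levels[findInterval(b, c(0, ec$cuts))]
    lp <- lp + outer(ec$x, lev)
  }
  rate <- exp(lp) * rep(h0, each = n)   # n x M
  seg_len <- diff(c(b, Inf))
  H <- rate * rep(seg_len, each = n)
  if (M > 1L) for (j in 2:M) H[, j] <- H[, j - 1L] + H[, j]
  cumH <- cbind(0, H)
  set.seed(str_seed(seed, "event_times"))
  E <- stats::rexp(n)
  seg <- vapply(seq_len(n),
                function(i) findInterval(E[i], cumH[i, ],
                                         rightmost.closed = FALSE),
                0L)
  seg <- pmin(seg, M)
  tev <- b[seg] + (E - cumH[cbind(seq_len(n), seg)]) / rate[cbind(seq_len(n), seg)]
  if (is.null(scenario$censoring)) {
    time <- tev; event <- rep(1L, n); cens <- rep(Inf, n)
  } else {
    set.seed(str_seed(seed, "censoring"))
    cens <- stats::runif(n, scenario$censoring[1], scenario$censoring[2])
    time <- pmin(tev, cens)
    event <- as.integer(tev <= cens)
  }
  df <- data.frame(id = seq_len(n), time = time, event = event)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  out <- survival_cohort(df, id = "id")
  attr(out, "latent") <- data.frame(event_time = tev, censor_time = cens)
  out
}

#' Preset scenario emulating a pediatric liver-transplant cancer cohort
#'
#' A 288-subject scenario shaped like a registry cohort of pediatric liver
#' transplant recipients with a cancer diagnosis: binary recipient/donor
#' covariates at registry frequencies (female 42%, positive CMV 28%,
#' ventilator use at transplant 5.6%), a four-level donor blood type
#' (O/A/B/AB at 62/30/7/0.7%), and a positive serum creatinine covariate
#' (lognormal, median 0.40 mg/dL).  Effects are qualitative imitations of
#' the cohort's fitted dynamics --- an early-positive, later-negative
#' ventilator effect, a donor-AB effect switching sign around two years,
#' constant creatinine and CMV effects --- and the baseline hazard and
#' uniform administrative censoring window are calibrated so that about
#' 51 of 288 subjects die.  The numeric effect levels are configuration
#' for validation studies, not estimates.
#'
#' @param n cohort size (default 288).
#' @return A [cohort_scenario()].
#' @export
transplant_scenario <- function(n = 288L) {
  cohort_scenario(
    n = n,
    baseline = list(cuts = 365, rates = c(1.5e-4, 5e-5)),
    covariates = list(
      female = list(type = "binary", p = 0.4201),
      cmv = list(type = "binary", p = 0.2813),
      ventilator = list(type = "binary", p = 0.0556),
      donor_bt = list(type = "categorical",
                      levels = c("O", "A", "B", "AB"),
                      probs = c(0.6215, 0.2951, 0.0729, 0.0069)),
      creatinine = list(type = "lognormal", meanlog = log(0.40),
                        sdlog = 0.5)),
    effects = list(
      creatinine = 1.6,
      cmv = 0.7,
      ventilator = list(cuts = 365, levels = c(1.2, -0.8)),
      female = list(cuts = 365, levels = c(0.6, -0.6)),
      donor_bt = list(A = -0.7, B = -0.35,
                      AB = list(cuts = 730, levels = c(-1.5, 2.5)))),
    censoring = c(30, 1500))
}

#' Mask covariate values missing-completely-at-random or missing-at-random
#'
#' MCAR masks exactly `round(fraction * n)` cells uniformly at random;
#' MAR masks with probability logistic in a named driver column, with the
#' intercept solved so the expected masked fraction equals `fraction`.
#'
#' @param x a `survcohort`.
#' @param column covariate column to mask.
#' @param fraction target masked fraction in (0, 1).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param driver for MAR, the column (covariate, `"time"` or `"event"`)
#'   driving missingness.
#' @param slope for MAR, log-odds slope per SD of the driver (default 2).
#' @param seed integer seed.
#' @return The cohort with masked cells set to `NA`.
#' @export
mask_missing <- function(x, column, fraction,
                         mechanism = c("MCAR", "MAR"), driver = NULL,
                         slope = 2, seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(fraction > 0, fraction < 1)
  covs <- attr(x, "covariates")
  if (!column %in% covs) stop("not a covariate column: ", column)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (mechanism == "MCAR") {
    idx <- sample.int(n, round(fraction * n))
  } else {
    if (is.null(driver) || !driver %in% names(x)) {
      stop("MAR masking needs an existing driver column")
    }
    z <- as.numeric(x[[driver]])
    z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * z)) -
                          fraction, c(-30, 30))$root
    idx <- which(stats::runif(n) < stats::plogis(a + slope * z))
  }
  x[[column]][idx] <- NA
  x
}
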