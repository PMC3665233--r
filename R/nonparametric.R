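#' Kaplan-Meier product-limit estimator
#'
#' Survival curve with jumps only at event times; censored subjects leave
#' the risk set without a jump.  A subject censored on the same day as a
#' death is still at risk at that death time (deaths are processed before
#' censorings).
#'
#' @param time follow-up times (days), or a `survcohort` object.
#' @param event 0/1 event indicators (ignored when `time` is a cohort).
#' @param conf if `TRUE`, add Greenwood standard errors and log-scale 95%
#'   confidence limits.
#' @return Object of class `km_curve`: data frame with one row per distinct
#'   event time (`time`, `n.risk`, `n.event`, `surv`, optionally `se`,
#'   `lower`, `upper`), with attribute `n`.
#' @examples
#' ab <- read_cohort(system.file("extdata", "ab_recipients.csv",
#'                               package = "graytvc"))
#' km_estimate(ab)        # a single jump at day 616
#' @export
km_estimate <- function(time, event = NULL, conf = FALSE) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time }
  stopifnot(length(time) >= 1L, length(time) == length(event))
  n <- length(time)
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    out <- data.frame(time = numeric(0), n.risk = integer(0),
                      n.event = integer(0), surv = numeric(0))
    return(structure(out, class = c("km_curve", "data.frame"), n = n))
  }
  r <- vapply(et, function(t) sum(time >= t), integer(1))
  d <- vapply(et, function(t) sum(time == t & event == 1), integer(1))
  s <- cumprod(1 - d / r)
  out <- data.frame(time = et, n.risk = r, n.event = d, surv = s)
  if (conf) {
    gw <- cumsum(d / (r * (r - d)))       # Greenwood
    out$se <- s * sqrt(gw)
    logse <- sqrt(gw)
    out$lower <- exp(log(s) - 1.96 * logse)
    out$upper <- pmin(exp(log(s) + 1.96 * logse), 1)
  }
  structure(out, class = c("km_curve", "data.frame"), n = n)
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step-function evaluation: `S(t) = 1` before the first event time.
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  if (nrow(km) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", attr(x, "n"), ", events =",
      sum(x$n.event), ", jumps at",
      paste(utils::head(x$time, 8), collapse = ", "),
      if (nrow(x) > 8) "...", "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (days)", ylab = "Survival",
                          xlim = NULL, ...) {
  tmax <- if (nrow(x)) max(x$time) * 1.05 else 1
  graphics::plot(c(0, x$time, tmax), c(1, x$surv, min(x$surv, 1)),
                 type = "s", ylim = c(0, 1), xlim = xlim,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Weighted logrank test across groups
#'
#' Standard weighted logrank family on the pooled distinct event times:
#' weight 1 per event time for the logrank test and the square root of the
#' number at risk for the Tarone-Ware test (which emphasises earlier
#' follow-up).  The chi-square statistic has `groups - 1` degrees of
#' freedom.
#'
#' @param time follow-up times, or a `survcohort`.
#' @param event 0/1 indicators.
#' @param group group labels (factor or vector); at least two non-empty
#'   groups.  When `time` is a cohort, `group` may name one of its
#'   covariate columns.
#' @param weight `"logrank"` or `"tarone-ware"`.
#' @return Object of class `grouped_survtest`: list with `statistic`,
#'   `df`, `p.value`, `weight`, and the per-group observed and expected
#'   event counts.
#' @export
weighted_logrank <- function(time, event = NULL, group = NULL,
                             weight = c("logrank", "tarone-ware")) {
  weight <- match.arg(weight)
  if (is.data.frame(time)) {
    if (is.character(group) && length(group) == 1L) group <- time[[group]]
    event <- time$event
    time <- time$time
  }
  g <- factor(group)
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    stop("need at least two non-empty groups")
  }
  if (sum(event) == 0L) stop("no events to compare")
  G <- nlevels(g)
  et <- sort(unique(time[event == 1]))
  U <- numeric(G)
  V <- matrix(0, G, G)
  O <- numeric(G); E <- numeric(G)
  for (t in et) {
    atrisk <- time >= t
    ni <- sum(atrisk)
    ngi <- vapply(levels(g), function(l) sum(atrisk & g == l), 0)
    dead <- time == t & event == 1
    di <- sum(dead)
    dgi <- vapply(levels(g), function(l) sum(dead & g == l), 0)
    w <- if (weight == "logrank") 1 else sqrt(ni)
    e <- di * ngi / ni
    U <- U + w * (dgi - e)
    O <- O + dgi; E <- E + e
    if (ni > 1L) {
      hyper <- di * (ni - di) / (ni - 1)
      V <- V + w^2 * hyper * (diag(ngi / ni) - tcrossprod(ngi / ni)) / 1
    }
  }
  keep <- seq_len(G - 1L)
  stat <- drop(crossprod(U[keep], solve_safe(V[keep, keep, drop = FALSE],
                                             U[keep])))
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = G - 1L,
                 p.value = stats::pchisq(stat, G - 1L, lower.tail = FALSE),
                 weight = weight, groups = levels(g),
                 observed = O, expected = E),
            class = "grouped_survtest")
}

#' @export
print.grouped_survtest <- function(x, ...) {
  cat(if (x$weight == "logrank") "Logrank" else "Tarone-Ware",
      "test: chi-square =", format(x$statistic, digits = 5),
      ", df =", x$df, ", p =", format.pval(x$p.value, digits = 3), "\n")
  print(data.frame(group = x$groups, observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  invisible(x)
}
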