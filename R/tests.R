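#' Wald test of overall covariate effect
#'
#' Tests that a covariate has no overall effect: for a time-varying column,
#' H0: all interval levels are zero, using the Wald-type statistic
#' `alpha' V^{-1} alpha` with `V` the column's block of the penalized
#' covariance `(I + P)^{-1}` and a chi-square reference with the column's
#' effective degrees of freedom (fractional df use the continuous gamma
#' form of the chi-square).  Under the null this quadratic form is a
#' weighted chi-square whose weights are the shrinkage eigenvalues of
#' `(I + P)^{-1} I`; they sum to the effective df, so the reference
#' matches the statistic's null mean and is slightly conservative in the
#' tail.  For a time-invariant column the test is the usual 1-df Wald
#' chi-square.
#'
#' @param fit a `gray_pctvc` fit.
#' @param covariate name of a coefficient column (an indicator of a factor
#'   block counts as one column, as reported by `summary()`).
#' @return Object of class `gray_htest` with `statistic`, `df`, `p.value`.
#' @export
test_overall <- function(fit, covariate) {
  stopifnot(inherits(fit, "gray_pctvc"))
  K <- fit$knots$K
  if (covariate %in% names(fit$alpha)) {
    j <- match(covariate, names(fit$alpha))
    idx <- (j - 1L) * K + seq_len(K)
    a <- fit$coefficients[idx]
    V <- fit$var[idx, idx, drop = FALSE]
    stat <- wald_quadform(a, V)
    df <- fit$edf[[covariate]]
  } else if (covariate %in% names(fit$gamma)) {
    idx <- length(fit$alpha) * K + match(covariate, names(fit$gamma))
    a <- fit$coefficients[idx]
    V <- fit$var[idx, idx, drop = FALSE]
    stat <- wald_quadform(a, V)
    df <- 1
  } else stop("unknown covariate: ", covariate)
  new_gray_htest("overall", covariate, stat, df)
}

#' Wald test of proportional hazards for one covariate
#'
#' Tests that a time-varying column's interval levels are all equal
#' (H0: `alpha_k = alpha_1` for all k), i.e. that the covariate satisfies
#' proportional hazards, via the Wald statistic on the successive
#' differences `C alpha` with variance `C V C'`, referenced to a
#' chi-square with `effective df - 1` degrees of freedom.
#'
#' @inheritParams test_overall
#' @return Object of class `gray_htest`.
#' @export
test_proportionality <- function(fit, covariate) {
  stopifnot(inherits(fit, "gray_pctvc"))
  K <- fit$knots$K
  if (!covariate %in% names(fit$alpha)) {
    stop("proportionality test applies to tv() covariates only: ", covariate)
  }
  if (K < 2L) stop("test undefined for K = 1")
  j <- match(covariate, names(fit$alpha))
  idx <- (j - 1L) * K + seq_len(K)
  C <- diff(diag(K))
  v <- drop(C %*% fit$coefficients[idx])
  Vc <- C %*% fit$var[idx, idx] %*% t(C)
  stat <- wald_quadform(v, Vc)
  df <- max(fit$edf[[covariate]] - 1, 1e-8)
  new_gray_htest("nonproportionality", covariate, stat, df)
}

wald_quadform <- function(a, V) {
  qi <- tryCatch(solve(V, a), error = function(e) {
    warning("singular test covariance; using pseudo-inverse")
    drop(MASS_ginv(V) %*% a)
  })
  max(drop(crossprod(a, qi)), 0)
}

new_gray_htest <- function(hypothesis, covariate, stat, df) {
  structure(list(hypothesis = hypothesis, covariate = covariate,
                 statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "gray_htest")
}

#' @export
print.gray_htest <- function(x, ...) {
  cat("Wald test (", x$hypothesis, ") for ", x$covariate, ": chi-square = ",
      format(x$statistic, digits = 4), ", df = ",
      format(x$df, digits = 4), ", p = ",
      format.pval(x$p.value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Step-function coefficient curve with pointwise confidence band
#'
#' The fitted log hazard ratio of a covariate as a right-continuous step
#' function over the knot intervals, with pointwise 95% band from the
#' penalized covariance.  Time-invariant covariates yield a single flat
#' segment.
#'
#' @inheritParams test_overall
#' @param level confidence level for the pointwise band.
#' @return Object of class `coefficient_curve`: data frame with columns
#'   `start`, `stop`, `estimate`, `se`, `lower`, `upper`, plus attributes
#'   `covariate`, `range` (min/max estimate).
#' @export
coefficient_curve <- function(fit, covariate, level = 0.95) {
  stopifnot(inherits(fit, "gray_pctvc"))
  K <- fit$knots$K
  tau <- fit$knots$tau
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (covariate %in% names(fit$alpha)) {
    j <- match(covariate, names(fit$alpha))
    idx <- (j - 1L) * K + seq_len(K)
    est <- unname(fit$coefficients[idx])
    se <- sqrt(pmax(diag(fit$var)[idx], 0))
    out <- data.frame(start = tau[-length(tau)], stop = tau[-1L],
                      estimate = est, se = se,
                      lower = est - z * se, upper = est + z * se)
  } else if (covariate %in% names(fit$gamma)) {
    idx <- length(fit$alpha) * K + match(covariate, names(fit$gamma))
    est <- unname(fit$coefficients[idx])
    se <- sqrt(max(diag(fit$var)[idx], 0))
    out <- data.frame(start = 0, stop = tau[length(tau)],
                      estimate = est, se = se,
                      lower = est - z * se, upper = est + z * se)
  } else stop("unknown covariate: ", covariate)
  structure(out, class = c("coefficient_curve", "data.frame"),
            covariate = covariate, range = range(out$estimate))
}

#' @export
plot.coefficient_curve <- function(x, xlab = "Time (days)",
                                   ylab = "Log hazard ratio", ...) {
  tgrid <- c(x$start, x$stop[nrow(x)])
  graphics::plot(tgrid, c(x$estimate, x$estimate[nrow(x)]), type = "s",
                 ylim = range(x$lower, x$upper, 0),
                 xlab = xlab, ylab = ylab,
                 main = attr(x, "covariate"), ...)
  graphics::lines(tgrid, c(x$lower, x$lower[nrow(x)]), type = "s", lty = 2)
  graphics::lines(tgrid, c(x$upper, x$upper[nrow(x)]), type = "s", lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
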