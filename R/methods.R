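# S3 methods for cox_efron and gray_pctvc fits.

#' @export
coef.cox_efron <- function(object, ...) object$coefficients

#' @export
coef.gray_pctvc <- function(object, ...) object$coefficients

#' @export
vcov.cox_efron <- function(object, ...) object$var

#' @export
vcov.gray_pctvc <- function(object, ...) object$var

#' @export
logLik.cox_efron <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
logLik.gray_pctvc <- function(object, ...) {
  structure(object$loglik,
            df = sum(object$edf) + length(object$gamma), class = "logLik")
}

#' @export
confint.cox_efron <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$var))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(b - z * se, b + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.cox_efron <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$nevent, "\n")
  print(summary(x)$coefficients, digits = 4)
  cat("Log partial likelihood:", format(x$loglik, digits = 6),
      " (null", format(x$loglik_null, digits = 6), ")\n")
  if (!x$converged) cat("NOT CONVERGED:", x$flag %||% "", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.cox_efron <- function(object, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$var))
  z <- b / se
  tab <- cbind(coef = b, `exp(coef)` = exp(b), se = se,
               lower95 = b - 1.96 * se, upper95 = b + 1.96 * se,
               z = z, p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, n = object$n, nevent = object$nevent,
                 loglik = object$loglik, loglik_null = object$loglik_null,
                 converged = object$converged, flag = object$flag,
                 call = object$call),
            class = "summary.cox_efron")
}

#' @export
print.summary.cox_efron <- function(x, ...) {
  cat("Call:", deparse(x$call), "\n")
  cat("n =", x$n, ", events =", x$nevent, "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                      digits = 4)
  invisible(x)
}

#' @export
print.gray_pctvc <- function(x, ...) {
  cat("Piecewise-constant time-varying coefficient fit: n =", x$n,
      ", events =", x$nevent, ", K =", x$knots$K, "interval(s)\n")
  if (length(x$alpha)) {
    cat("Time-varying terms:", paste(names(x$alpha), collapse = ", "), "\n")
    cat("Effective df:", paste(sprintf("%s=%.2f", names(x$edf), x$edf),
                               collapse = ", "), "\n")
  }
  if (length(x$gamma)) {
    cat("Time-invariant terms:", paste(sprintf("%s=%.3f", names(x$gamma),
                                               x$gamma), collapse = ", "), "\n")
  }
  cat("Penalized log partial likelihood:",
      format(x$penalized_loglik, digits = 6), "\n")
  if (!x$converged) cat("NOT CONVERGED:", x$flag %||% "", "\n")
  invisible(x)
}

#' Summarise a PC-TVC fit
#'
#' One row per coefficient column: for time-varying columns the minimum
#' and maximum interval log hazard ratio, the overall-effect p-value and
#' the nonproportionality p-value; for time-invariant columns the
#' estimate, 95% confidence interval and Wald p-value.
#'
#' @param object a `gray_pctvc` fit.
#' @param ... unused.
#' @export
summary.gray_pctvc <- function(object, ...) {
  K <- object$knots$K
  rows <- list()
  for (nm in names(object$alpha)) {
    ov <- test_overall(object, nm)
    np <- if (K >= 2L) test_proportionality(object, nm) else NULL
    rows[[nm]] <- data.frame(
      covariate = nm, type = "tv",
      min = min(object$alpha[[nm]]), max = max(object$alpha[[nm]]),
      edf = unname(object$edf[nm]),
      p_overall = ov$p.value,
      p_nonprop = if (is.null(np)) NA_real_ else np$p.value)
  }
  for (nm in names(object$gamma)) {
    ov <- test_overall(object, nm)
    est <- unname(object$gamma[nm])
    se <- sqrt(diag(object$var))[length(object$alpha) * K +
                                   match(nm, names(object$gamma))]
    rows[[nm]] <- data.frame(
      covariate = nm, type = "fixed",
      min = est - 1.96 * se, max = est + 1.96 * se, edf = 1,
      p_overall = ov$p.value, p_nonprop = NA_real_)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n = object$n, nevent = object$nevent,
                 K = K, lambda = object$lambda,
                 loglik = object$loglik, converged = object$converged,
                 call = object$call),
            class = "summary.gray_pctvc")
}

#' @export
print.summary.gray_pctvc <- function(x, digits = 4, ...) {
  cat("Call:", deparse(x$call), "\n")
  cat("n =", x$n, ", events =", x$nevent, ", K =", x$K, "\n")
  cat("(tv rows: min/max interval log hazard ratio;",
      "fixed rows: estimate 95% CI bounds)\n\n")
  tab <- x$table
  tab$min <- signif(tab$min, digits); tab$max <- signif(tab$max, digits)
  tab$edf <- round(tab$edf, 2)
  tab$p_overall <- signif(tab$p_overall, 3)
  tab$p_nonprop <- signif(tab$p_nonprop, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# design matrices for new data, in the training column order
design_for <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  mf <- tryCatch(
    stats::model.frame(tt, as.data.frame(newdata), na.action = stats::na.pass,
                       xlev = object$xlevels),
    error = function(e) stop("newdata incompatible with fit: ",
                             conditionMessage(e)))
  mm <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
  asg <- attr(mm, "assign")
  mm <- mm[, asg != 0L, drop = FALSE]
  colnames(mm) <- vapply(colnames(mm), clean_tv_name, "")
  mm
}

# survival matrix (subjects x times) for either fit class
predict_surv_matrix <- function(object, Xn, Zn, times) {
  bh <- object$baseline
  E <- length(bh$time)
  n <- max(nrow(Xn), nrow(Zn))
  if (inherits(object, "gray_pctvc") && length(object$alpha)) {
    A <- do.call(cbind, object$alpha)          # K x ptv
    lp <- (Xn %*% t(A))[, bh$interval, drop = FALSE]
  } else {
    lp <- matrix(0, n, E)
  }
  if (!is.null(Zn) && ncol(Zn)) {
    gam <- if (inherits(object, "gray_pctvc")) object$gamma else
      object$coefficients
    lp <- lp + drop(Zn %*% gam)
  }
  W <- exp(lp) * rep(bh$hazard, each = n)
  Ind <- outer(bh$time, times, "<=") + 0
  S <- exp(-(W %*% Ind))
  dimnames(S) <- list(NULL, paste0("t", times))
  S
}

#' Predicted survival and linear predictors
#'
#' For `type = "survival"`, the Breslow-type model-based survival
#' `S(t | x) = exp(-sum_{t_i <= t} dH0(t_i) exp(beta(t_i)' x))` at the
#' requested times.  Times beyond the last knot (the maximum observed
#' failure time) are flagged as extrapolation with a warning.
#'
#' @param object a `gray_pctvc` fit.
#' @param newdata data frame of covariates; default the training data.
#' @param times evaluation times (days); default the distinct event times.
#' @param type `"survival"` (matrix subjects x times) or `"lp"` (matrix of
#'   per-interval linear predictors).
#' @param ... unused.
#' @export
predict.gray_pctvc <- function(object, newdata = NULL, times = NULL,
                               type = c("survival", "lp"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Xn <- object$X; Zn <- object$Z
  } else {
    mm <- design_for(object, newdata)
    Xn <- mm[, colnames(object$X), drop = FALSE]
    Zn <- mm[, colnames(object$Z), drop = FALSE]
  }
  if (type == "lp") {
    if (length(object$alpha)) {
      A <- do.call(cbind, object$alpha)
      out <- Xn %*% t(A)
      colnames(out) <- paste0("interval", seq_len(object$knots$K))
    } else out <- matrix(0, nrow(Zn), object$knots$K)
    if (ncol(Zn)) out <- out + drop(Zn %*% object$gamma)
    return(out)
  }
  Tmax <- object$knots$tau[length(object$knots$tau)]
  if (is.null(times)) times <- object$baseline$time
  if (any(times > Tmax)) {
    warning("extrapolation: ", sum(times > Tmax),
            " time(s) beyond the last knot T = ", Tmax)
  }
  predict_surv_matrix(object, Xn, Zn, times)
}

#' @rdname predict.gray_pctvc
#' @export
predict.cox_efron <- function(object, newdata = NULL, times = NULL,
                              type = c("survival", "lp"), ...) {
  type <- match.arg(type)
  Zn <- if (is.null(newdata)) object$X else {
    design_for(object, newdata)[, names(object$coefficients), drop = FALSE]
  }
  if (type == "lp") return(drop(Zn %*% object$coefficients))
  if (is.null(times)) times <- object$baseline$time
  predict_surv_matrix(object, Xn = matrix(0, nrow(Zn), 0), Zn = Zn, times)
}

#' Plot the fitted step coefficient curves
#'
#' One panel per time-varying term showing the piecewise-constant log
#' hazard ratio with its pointwise 95% band.
#'
#' @param x a `gray_pctvc` fit.
#' @param covariates columns to plot; default all time-varying columns.
#' @param ... passed to [plot.coefficient_curve()].
#' @export
plot.gray_pctvc <- function(x, covariates = names(x$alpha), ...) {
  if (!length(covariates)) stop("no time-varying terms to plot")
  if (length(covariates) > 1L) {
    op <- graphics::par(mfrow = grDevices::n2mfrow(length(covariates)))
    on.exit(graphics::par(op))
  }
  for (nm in covariates) plot(coefficient_curve(x, nm), ...)
  invisible(x)
}
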