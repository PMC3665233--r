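#' Jackknife pseudo-observations of survival
#'
#' Leave-one-out transform of the Kaplan-Meier estimator:
#' `pv_i(t) = n * S(t) - (n - 1) * S^(-i)(t)`, where `S` is the KM
#' estimate on the full sample and `S^(-i)` omits subject `i`.  With no
#' censoring, `pv_i(t)` equals the indicator `1[time_i > t]`, and at any
#' censoring pattern the subject mean of the pseudo-values reproduces
#' `S(t)` exactly.
#'
#' @param time follow-up times, or a `survcohort`.
#' @param event 0/1 indicators.
#' @param timepoints evaluation times; default the nine deciles
#'   (10%...90%) of the observed event times.
#' @return Matrix (subjects x timepoints) of pseudo-values, with the
#'   timepoints as an attribute and in the column names.
#' @export
pseudo_values <- function(time, event = NULL, timepoints = NULL) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time }
  n <- length(time)
  if (is.null(timepoints)) timepoints <- default_timepoints(time, event)
  if (any(timepoints > max(time))) {
    warning("timepoint(s) beyond the last observed follow-up time")
  }
  et <- sort(unique(time[event == 1]))
  r <- vapply(et, function(t) sum(time >= t), 0)
  d <- vapply(et, function(t) sum(time == t & event == 1), 0)
  cuml <- function(dd, rr) {
    frac <- ifelse(dd == 0, 0, dd / rr)          # rr=0 only where dd=0
    lg <- ifelse(frac >= 1, -Inf, log1p(-frac))
    cumsum(lg)
  }
  Sfull_steps <- exp(cuml(d, r))
  step_at <- function(steps, t) c(1, steps)[findInterval(t, et) + 1L]
  Sfull <- step_at(Sfull_steps, timepoints)
  pv <- matrix(NA_real_, n, length(timepoints))
  for (i in seq_len(n)) {
    ri <- r - (time[i] >= et)
    di <- d
    if (event[i] == 1) di[et == time[i]] <- di[et == time[i]] - 1
    Si <- step_at(exp(cuml(di, ri)), timepoints)
    pv[i, ] <- n * Sfull - (n - 1) * Si
  }
  colnames(pv) <- paste0("t", signif(timepoints, 6))
  attr(pv, "timepoints") <- timepoints
  attr(pv, "km") <- Sfull
  pv
}

default_timepoints <- function(time, event) {
  tt <- time[event == 1]
  if (length(tt) == 0L) stop("no events")
  unname(stats::quantile(tt, probs = seq(0.1, 0.9, by = 0.1), type = 1))
}

#' Pseudo-residual goodness-of-fit summary
#'
#' For each of the preselected time points, compares the jackknife
#' pseudo-values of survival with the model-predicted survival
#' `S(t | x_i)`: `residual_i(t) = pv_i(t) - S_fit(t | x_i)`.  At each
#' time point the residuals are lowess-smoothed against the predicted
#' survival; under a well-specified model the smoothed curves stay around
#' zero, and systematic departure indicates lack of fit.  The scalar
#' summary per time point is the mean absolute value of the smoothed
#' curve over the central 80% of the predicted-survival range (the signed
#' mean cancels misfit that goes opposite ways for low- and high-risk
#' subjects, and the curve's extremes are lowess extrapolation noise);
#' the overall summary is the maximum over time points.
#'
#' @param fit a `gray_pctvc` or `cox_efron` fit.
#' @param timepoints evaluation times; default the nine deciles of the
#'   observed event times.
#' @param span lowess span (default 2/3).
#' @param iter lowess robustness iterations.  The default 0 performs the
#'   single local-regression pass: pseudo-values are near-binary at early
#'   time points, and robust reweighting would downweight the minority
#'   class (the deaths) and bias the smooth toward the majority.
#' @return Object of class `pseudo_gof`: list with `timepoints`,
#'   `pseudo`, `predicted`, `residuals` (matrices subjects x timepoints),
#'   `smoothed` (list of lowess curves), `mean_smooth` (signed mean of
#'   each curve), `abs_smooth` (central mean absolute smoothed residual
#'   per time point), and `max_abs_mean_smooth = max(abs_smooth)`.
#' @export
pseudo_residuals <- function(fit, timepoints = NULL, span = 2 / 3,
                             iter = 0L) {
  stopifnot(inherits(fit, c("gray_pctvc", "cox_efron")))
  time <- fit$time; event <- fit$event
  if (is.null(timepoints)) timepoints <- default_timepoints(time, event)
  pv <- pseudo_values(time, event, timepoints)
  pred <- suppressWarnings(predict(fit, times = timepoints))
  res <- pv - pred
  sm <- vector("list", length(timepoints))
  mean_sm <- abs_sm <- numeric(length(timepoints))
  for (j in seq_along(timepoints)) {
    lw <- stats::lowess(pred[, j], res[, j], f = span, iter = iter)
    sm[[j]] <- lw
    mean_sm[j] <- mean(lw$y)
    qs <- stats::quantile(pred[, j], c(0.1, 0.9))
    keep <- lw$x >= qs[1L] & lw$x <= qs[2L]
    if (!any(keep)) keep <- rep(TRUE, length(lw$x))
    abs_sm[j] <- mean(abs(lw$y[keep]))
  }
  structure(list(timepoints = timepoints, pseudo = pv, predicted = pred,
                 residuals = res, smoothed = sm, mean_smooth = mean_sm,
                 abs_smooth = abs_sm,
                 max_abs_mean_smooth = max(abs_sm)),
            class = "pseudo_gof")
}

#' @export
print.pseudo_gof <- function(x, ...) {
  cat("Pseudo-residual goodness of fit at", length(x$timepoints),
      "time points\n")
  print(data.frame(timepoint = signif(x$timepoints, 5),
                   mean_smoothed = signif(x$mean_smooth, 3),
                   central_abs_smoothed = signif(x$abs_smooth, 3)),
        row.names = FALSE)
  cat("Max central |smoothed residual| over time points:",
      signif(x$max_abs_mean_smooth, 4), "\n")
  invisible(x)
}

#' @export
plot.pseudo_gof <- function(x, which = seq_along(x$timepoints), ...) {
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
    on.exit(graphics::par(op))
  }
  for (j in which) {
    graphics::plot(x$predicted[, j], x$residuals[, j], pch = 16,
                   cex = 0.4, col = "grey40",
                   xlab = "Predicted survival", ylab = "Pseudo-residual",
                   main = paste0("t = ", signif(x$timepoints[j], 5)), ...)
    graphics::lines(x$smoothed[[j]], col = "red", lwd = 2)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' @export
residuals.gray_pctvc <- function(object, timepoints = NULL, ...) {
  pseudo_residuals(object, timepoints = timepoints, ...)
}

#' @export
residuals.cox_efron <- function(object, timepoints = NULL, ...) {
  pseudo_residuals(object, timepoints = timepoints, ...)
}
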