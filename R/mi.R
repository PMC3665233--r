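# Multiple imputation by chained equations with posterior draws, and
# Rubin's-rules pooling (D2 combination for chi-square tests).

#' Multiply impute missing covariate values
#'
#' Chained conditional imputation under a missing-at-random assumption:
#' each incomplete covariate is regressed on the other covariates plus the
#' event indicator and log follow-up time, and missing cells are replaced
#' by posterior-predictive draws --- a Bayesian normal linear model for
#' continuous columns, logistic regression with a normal approximation to
#' the coefficient posterior for binary columns, and multinomial logistic
#' regression for factors with more than two levels.  Missingness must be
#' confined to covariates.
#'
#' @param x a `survcohort` with missing covariate cells.
#' @param m number of completed datasets (default 5).
#' @param seed integer seed; makes the output reproducible.
#' @param cycles chained-equation sweeps per imputation (default 5).
#' @return List of `m` completed `survcohort`s, class `mi_cohorts`.
#' @export
impute_cohort <- function(x, m = 5L, seed = NULL, cycles = 5L) {
  covs <- attr(x, "covariates")
  df <- as.data.frame(x)
  incomplete <- covs[vapply(covs, function(nm) anyNA(df[[nm]]), TRUE)]
  fully_missing <- incomplete[vapply(incomplete,
                                     function(nm) all(is.na(df[[nm]])), TRUE)]
  if (length(fully_missing)) {
    stop("column(s) fully missing: ", paste(fully_missing, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  if (!length(incomplete)) {
    out <- replicate(m, x, simplify = FALSE)
    return(structure(out, class = "mi_cohorts", m = m, imputed = character(0)))
  }
  aux <- data.frame(.event = df$event, .logtime = log(df$time))
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    cur <- df
    for (nm in incomplete) {          # initialise from observed margins
      miss <- is.na(cur[[nm]])
      cur[[nm]][miss] <- sample(cur[[nm]][!miss], sum(miss), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (nm in incomplete) {
        miss <- is.na(df[[nm]])
        preds <- setdiff(covs, nm)
        D <- cbind(aux, cur[preds])
        cur[[nm]][miss] <- draw_imputations(df[[nm]], cur[[nm]], miss, D)
      }
    }
    out[[imp]] <- survival_cohort(cur, time = "time", event = "event",
                                  id = "id")
  }
  structure(out, class = "mi_cohorts", m = m, imputed = incomplete)
}

# posterior-predictive draw for the missing cells of one column
draw_imputations <- function(orig, current, miss, D) {
  Dm <- stats::model.matrix(~ ., data = D)
  yobs <- current[!miss]
  Xo <- Dm[!miss, , drop = FALSE]
  Xm <- Dm[miss, , drop = FALSE]
  keep <- qr(Xo)$pivot[seq_len(qr(Xo)$rank)]
  Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
  if (is.factor(orig)) {
    if (nlevels(orig) == 2L) {
      yb <- as.integer(yobs == levels(orig)[2L])
      fit <- suppressWarnings(stats::glm.fit(Xo, yb,
                                             family = stats::binomial()))
      bstar <- draw_coef(fit$coefficients, glm_vcov(fit, Xo))
      p <- stats::plogis(drop(Xm %*% bstar))
      factor(levels(orig)[1L + stats::rbinom(nrow(Xm), 1L, p)],
             levels = levels(orig))
    } else {
      dd <- data.frame(y = yobs, Xo[, -1L, drop = FALSE])
      fit <- nnet::multinom(y ~ ., data = dd, trace = FALSE)
      co <- stats::coef(fit)
      vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      cv <- as.vector(t(co))
      cstar <- if (is.null(vc)) cv else draw_coef(cv, vc)
      B <- matrix(cstar, nrow = nrow(co), byrow = TRUE)
      eta <- cbind(0, Xm %*% t(B))
      pr <- exp(eta - apply(eta, 1L, max))
      pr <- pr / rowSums(pr)
      idx <- apply(pr, 1L, function(p) sample.int(length(p), 1L, prob = p))
      factor(levels(orig)[idx], levels = levels(orig))
    }
  } else {
    # Bayesian linear regression draw
    qrx <- qr(Xo)
    bhat <- qr.coef(qrx, yobs)
    resid <- yobs - drop(Xo %*% bhat)
    dfree <- max(length(yobs) - ncol(Xo), 1L)
    s2 <- sum(resid^2) / stats::rchisq(1L, dfree)
    R <- qr.R(qrx)
    V <- chol2inv(R) * s2
    bstar <- draw_coef(bhat, V)
    drop(Xm %*% bstar) + stats::rnorm(nrow(Xm), 0, sqrt(s2))
  }
}

draw_coef <- function(b, V) {
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e) {
    ev <- eigen(V, symmetric = TRUE)
    ev$values <- pmax(ev$values, 0)
    ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  })
  b + drop(t(ch) %*% stats::rnorm(length(b)))
}

glm_vcov <- function(fit, X) {
  w <- fit$weights
  XtWX <- crossprod(X * w, X)
  tryCatch(solve(XtWX), error = function(e) MASS_ginv(XtWX))
}

#' Pool fitted models across imputations by Rubin's rules
#'
#' Coefficients are pooled as the mean estimate with total variance
#' `T = W + (1 + 1/m) B` (`W` the mean within-imputation variance, `B`
#' the between-imputation variance) and Barnard-Rubin small-sample
#' degrees of freedom.  For `gray_pctvc` fits, the overall-effect and
#' nonproportionality chi-square tests are combined by the D2 method
#' (pooling the chi-square statistics with an F reference).
#'
#' @param fits list of `m` fitted models (`cox_efron` or `gray_pctvc`)
#'   with identical specifications.
#' @return For `m = 1` the single fit unchanged; otherwise an object of
#'   class `pooled_fit` with a per-coefficient table and, for Gray fits,
#'   pooled test p-values.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  stopifnot(m >= 1L)
  if (m == 1L) return(fits[[1L]])
  cls <- class(fits[[1L]])[1L]
  cn <- names(stats::coef(fits[[1L]]))
  for (f in fits) {
    if (!identical(class(f)[1L], cls) ||
        !identical(names(stats::coef(f)), cn)) {
      stop("fits have mismatched specifications")
    }
  }
  Q <- do.call(rbind, lapply(fits, function(f) unname(stats::coef(f))))
  U <- do.call(rbind, lapply(fits, function(f) unname(diag(stats::vcov(f)))))
  qbar <- colMeans(Q)
  W <- colMeans(U)
  B <- apply(Q, 2L, stats::var)
  Tv <- W + (1 + 1 / m) * B
  ncom <- fits[[1L]]$n - length(cn)
  lam <- pmin(pmax((1 + 1 / m) * B / Tv, 1e-12), 1 - 1e-12)
  nu_old <- (m - 1) / lam^2
  nu_obs <- (ncom + 1) / (ncom + 3) * ncom * (1 - lam)
  nu <- nu_old * nu_obs / (nu_old + nu_obs)
  tstat <- qbar / sqrt(Tv)
  ptab <- data.frame(coefficient = cn, estimate = qbar, W = W, B = B,
                     total_var = Tv, df = nu,
                     p = 2 * stats::pt(-abs(tstat), nu))
  tests <- NULL
  if (cls == "gray_pctvc") {
    tests <- pool_gray_tests(fits)
  }
  structure(list(m = m, model = cls, coefficients = ptab, tests = tests),
            class = "pooled_fit")
}

pool_gray_tests <- function(fits) {
  f1 <- fits[[1L]]
  rows <- list()
  for (nm in names(f1$alpha)) {
    for (hyp in c("overall", "nonproportionality")) {
      tf <- if (hyp == "overall") test_overall else test_proportionality
      if (hyp == "nonproportionality" && f1$knots$K < 2L) next
      ds <- vapply(fits, function(f) tf(f, nm)$statistic, 0)
      ks <- vapply(fits, function(f) tf(f, nm)$df, 0)
      res <- pool_d2(ds, mean(ks))
      rows[[paste(nm, hyp)]] <- data.frame(
        covariate = nm, hypothesis = hyp, statistic = res$D2,
        df1 = res$k, df2 = res$nu, p = res$p)
    }
  }
  for (nm in names(f1$gamma)) {
    ds <- vapply(fits, function(f) test_overall(f, nm)$statistic, 0)
    res <- pool_d2(ds, 1)
    rows[[paste(nm, "overall")]] <- data.frame(
      covariate = nm, hypothesis = "overall", statistic = res$D2,
      df1 = res$k, df2 = res$nu, p = res$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Li-Meng-Raghunathan-Rubin D2 combination of chi-square statistics
pool_d2 <- function(d, k) {
  m <- length(d)
  r <- (1 + 1 / m) * stats::var(sqrt(d))
  if (!is.finite(r) || r < 0) r <- 0
  D2 <- (mean(d) / k - (m + 1) / (m - 1) * r) / (1 + r)
  D2 <- max(D2, 0)
  nu <- if (r > 0) k^(-3 / m) * (m - 1) * (1 + 1 / r)^2 else Inf
  p <- stats::pf(D2, k, nu, lower.tail = FALSE)
  list(D2 = D2, k = k, nu = nu, p = p)
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("Rubin's-rules pooling of", x$m, x$model, "fits\n\n")
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], signif, 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPooled tests (D2):\n")
    tt <- x$tests
    tt[3:6] <- lapply(tt[3:6], signif, 4)
    print(tt, row.names = FALSE)
  }
  invisible(x)
}
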