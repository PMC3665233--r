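#' Mark a model term as time-varying
#'
#' Used inside a [pctvc()] formula to request a piecewise-constant
#' time-varying coefficient for a term, e.g.
#' `Surv(time, event) ~ tv(ventilator) + creatinine`.  Factors wrapped in
#' `tv()` expand to reference-coded indicator columns that form a block
#' sharing one smoothing parameter.
#'
#' @param x a covariate (numeric or factor).
#' @return `x` unchanged; the wrapper is only a formula marker.
#' @export
tv <- function(x) x

# --- formula plumbing ------------------------------------------------------

clean_tv_name <- function(nm) {
  sub("^tv\\((.*)\\)(.*)$", "\\1\\2", nm)
}

parse_surv_formula <- function(formula, data, allow_tv = TRUE) {
  data <- as.data.frame(data)
  mt <- stats::terms(formula, specials = "tv", data = data)
  if (!attr(mt, "response")) stop("formula needs a Surv(time, event) response")
  mf <- stats::model.frame(mt, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right") {
    stop("response must be a right-censored survival::Surv(time, event) object")
  }
  time <- as.numeric(y[, 1L])
  event <- as.integer(y[, 2L])
  if (any(time <= 0)) stop("nonpositive follow-up time")
  mm <- stats::model.matrix(mt, mf)
  asg <- attr(mm, "assign")
  keep <- asg != 0L
  mm <- mm[, keep, drop = FALSE]
  asg <- asg[keep]
  if (anyNA(mm)) {
    stop("missing covariate values; use complete_cases() or impute_cohort() first")
  }
  labels <- attr(mt, "term.labels")
  tvinfo <- survival::untangle.specials(mt, "tv", order = 1L)
  tv_terms <- tvinfo$terms
  if (!allow_tv && length(tv_terms)) {
    stop("tv() terms are not allowed here; all effects are time-invariant")
  }
  colnames(mm) <- vapply(colnames(mm), clean_tv_name, "")
  is_tv_col <- asg %in% tv_terms
  X <- mm[, is_tv_col, drop = FALSE]
  Z <- mm[, !is_tv_col, drop = FALSE]
  blocks <- lapply(seq_along(labels), function(tn) {
    tvb <- tn %in% tv_terms
    cols <- colnames(mm)[asg == tn]
    list(label = clean_tv_name(labels[tn]), tv = tvb, cols = cols,
         idx = if (tvb) match(cols, colnames(X)) else match(cols, colnames(Z)))
  })
  names(blocks) <- vapply(blocks, `[[`, "", "label")
  check_variation <- function(M) {
    if (ncol(M)) {
      v <- apply(M, 2L, stats::sd)
      if (any(v == 0)) stop("no variation in covariate(s): ",
                            paste(colnames(M)[v == 0], collapse = ", "))
    }
  }
  check_variation(X); check_variation(Z)
  list(time = time, event = event, X = X, Z = Z, blocks = blocks,
       terms = mt, xlevels = stats::.getXlevels(mt, mf),
       contrasts = attr(mm, "contrasts"))
}

#' Control parameters for the penalized Newton-Raphson fitter
#'
#' @param grad_tol convergence when the largest absolute score component
#'   falls below this value.
#' @param rel_tol alternative convergence on the relative change of the
#'   (penalized) log partial likelihood.
#' @param maxit maximum Newton-Raphson iterations.
#' @param sep_limit coefficient magnitude beyond which a still-improving
#'   likelihood is flagged as monotone (separation) and the fit marked
#'   non-converged.
#' @param df_tol tolerance for matching a per-covariate effective-df target.
#' @param outer_maxit maximum coordinate-descent sweeps over the smoothing
#'   parameters.
#' @return A list of control values.
#' @export
pctvc_control <- function(grad_tol = 1e-8, rel_tol = 1e-10, maxit = 50L,
                          sep_limit = 15, df_tol = 0.01, outer_maxit = 25L) {
  list(grad_tol = grad_tol, rel_tol = rel_tol, maxit = as.integer(maxit),
       sep_limit = sep_limit, df_tol = df_tol,
       outer_maxit = as.integer(outer_maxit))
}

# per-tv-column effective df: trace of the column's K-block of (I+P)^{-1} I
edf_columns <- function(info, P, ptv, K) {
  if (!ptv) return(numeric(0))
  M <- tryCatch(solve(info + P, info), error = function(e) {
    MASS_ginv(info + P) %*% info
  })
  dg <- diag(M)
  vapply(seq_len(ptv), function(j) sum(dg[(j - 1L) * K + seq_len(K)]), 0)
}

#' Fit Gray's piecewise-constant time-varying coefficient model
#'
#' Maximises the penalized Efron log partial likelihood
#' `l(alpha) - sum_j (lambda_j / 2) * sum_k (alpha_jk - alpha_{j,k-1})^2`
#' where each `tv()` term's log hazard ratio is a right-continuous step
#' function over `K` knot intervals and the first-difference penalty
#' shrinks its jumps.  Terms not wrapped in `tv()` get single unpenalized
#' (time-invariant) coefficients, giving the mixed fit.  Smoothing
#' parameters are solved coordinate-wise by bisection on `log(lambda)` so
#' that each term's effective degrees of freedom --- the trace of its block
#' of `(I + P)^{-1} I`, `I` the unpenalized observed information and `P`
#' the penalty --- matches `df` (a factor block shares one lambda and
#' targets `df` per indicator column).  With `lambda = 0` the model is the
#' unpenalized interval-by-covariate fit; as `lambda -> Inf` it collapses
#' to the Cox proportional-hazards model.
#'
#' @param formula `Surv(time, event) ~ tv(x1) + x2 + ...`; see [tv()].
#' @param data data frame or `survcohort`.
#' @param df target effective degrees of freedom per time-varying term
#'   (default 4); ignored when `lambda` is supplied.  Values above `K` are
#'   capped at `K`.
#' @param K number of knot intervals for [place_knots()]; default
#'   `max(2, min(10, ceiling(events / 8)))`.
#' @param knots a [knot_set()] or numeric vector of interior knots,
#'   overriding `K`.
#' @param lambda optional fixed smoothing parameter(s), one per `tv()`
#'   term (recycled); bypasses the df search.
#' @param control see [pctvc_control()].
#' @return Object of class `gray_pctvc` with components including
#'   `coefficients`, `alpha` (list of per-interval levels per time-varying
#'   column), `gamma` (time-invariant coefficients), `knots`, `lambda`,
#'   `edf`, `var` (penalized covariance, used for tests and bands),
#'   `var_sandwich` (frequentist sandwich), `loglik`, `baseline`.
#' @examples
#' set.seed(1)
#' d <- data.frame(time = rexp(120, 0.1), event = rbinom(120, 1, 0.8),
#'                 x = rnorm(120))
#' f <- pctvc(survival::Surv(time, event) ~ tv(x), d, df = 2, K = 3)
#' summary(f)
#' @export
pctvc <- function(formula, data, df = 4, K = NULL, knots = NULL,
                  lambda = NULL, control = pctvc_control()) {
  cl <- match.call()
  pf <- parse_surv_formula(formula, data, allow_tv = TRUE)
  kn <- if (is.null(knots)) {
    place_knots(data.frame(time = pf$time, event = pf$event), K = K)
  } else if (inherits(knots, "knot_set")) knots else {
    knot_set(as.numeric(knots), max(pf$time[pf$event == 1]))
  }
  Kn <- kn$K
  st <- pl_prepare(pf$time, pf$event, pf$X, pf$Z, kn$tau)
  ptv <- st$ptv
  tv_blocks <- Filter(function(b) b$tv, pf$blocks)
  nb <- length(tv_blocks)

  block_lambda_to_cols <- function(lam_b) {
    lam <- numeric(ptv)
    for (i in seq_len(nb)) lam[tv_blocks[[i]]$idx] <- lam_b[i]
    lam
  }
  fit_at <- function(lam_b, theta0 = NULL) {
    P <- penalty_matrix(ptv, Kn, st$pf, block_lambda_to_cols(lam_b))
    fr <- pl_fit(st, P, theta0, control = control)
    fr$P <- P
    fr$df_cols <- edf_columns(fr$info, P, ptv, Kn)
    fr
  }
  block_df <- function(fr, i) sum(fr$df_cols[tv_blocks[[i]]$idx])

  if (nb == 0L || Kn == 1L) {
    lam_b <- rep(0, max(nb, 0L))
    fr <- fit_at(lam_b)
  } else if (!is.null(lambda)) {
    if (any(lambda < 0)) stop("lambda must be nonnegative")
    lam_b <- rep_len(as.numeric(lambda), nb)
    fr <- fit_at(lam_b)
  } else {
    target <- rep_len(as.numeric(df), nb)
    if (any(target < 1)) stop("df must be >= 1")
    capped <- target > Kn
    if (any(capped)) {
      warning("target df exceeds K = ", Kn, " for ",
              paste(names(tv_blocks)[capped], collapse = ", "),
              "; capped at K")
      target[capped] <- Kn
    }
    ndum <- vapply(tv_blocks, function(b) length(b$idx), 0L)
    target_block <- target * ndum           # block trace target
    tol_block <- control$df_tol * ndum
    lam_b <- ifelse(target >= Kn - 1e-9, 0, 1)
    fr <- fit_at(lam_b)
    for (sweep in seq_len(control$outer_maxit)) {
      moved <- FALSE
      for (i in seq_len(nb)) {
        if (target[i] >= Kn - 1e-9) { lam_b[i] <- 0; next }
        g <- function(lam) {
          lb <- lam_b; lb[i] <- lam
          fr <<- fit_at(lb, fr$theta)
          block_df(fr, i)
        }
        cur <- block_df(fr, i)
        if (abs(cur - target_block[i]) <= tol_block[i]) next
        moved <- TRUE
        lo <- 1e-8; hi <- max(lam_b[i], 1e-4)
        while (g(hi) > target_block[i] && hi < 1e12) hi <- hi * 10
        if (hi >= 1e12 && block_df(fr, i) > target_block[i] + tol_block[i]) {
          warning("df target ", target[i], " unattainable for ",
                  names(tv_blocks)[i], "; lambda capped at 1e12")
          lam_b[i] <- hi
          next
        }
        mid <- hi
        for (bi in seq_len(60L)) {
          mid <- sqrt(lo * hi)
          val <- g(mid)
          if (abs(val - target_block[i]) <= tol_block[i]) break
          if (val > target_block[i]) lo <- mid else hi <- mid
        }
        lam_b[i] <- mid
      }
      done <- all(vapply(seq_len(nb), function(i) {
        target[i] >= Kn - 1e-9 ||
          abs(block_df(fr, i) - target_block[i]) <= tol_block[i]
      }, TRUE))
      if (done && !moved) break
      if (done && sweep > 1L) break
    }
  }

  P <- fr$P
  Ip <- fr$info + P
  bread <- tryCatch(solve(Ip), error = function(e) MASS_ginv(Ip))
  bread <- (bread + t(bread)) / 2           # penalized (Bayesian) covariance
  var_sand <- bread %*% fr$info %*% bread   # frequentist sandwich
  var_sand <- (var_sand + t(var_sand)) / 2

  theta <- fr$theta
  cn <- c(if (ptv) as.vector(t(outer(colnames(pf$X), seq_len(Kn),
                                     function(a, b) paste0(a, ":", b)))),
          colnames(pf$Z))
  names(theta) <- cn
  dimnames(var_sand) <- list(cn, cn)
  dimnames(bread) <- list(cn, cn)
  alpha <- if (ptv) {
    a <- lapply(seq_len(ptv), function(j) theta[(j - 1L) * Kn + seq_len(Kn)])
    names(a) <- colnames(pf$X)
    a
  } else list()
  gamma <- if (st$pf) {
    g <- theta[ptv * Kn + seq_len(st$pf)]
    names(g) <- colnames(pf$Z)
    g
  } else numeric(0)
  edf_col <- fr$df_cols
  names(edf_col) <- colnames(pf$X)
  lam_named <- if (nb) stats::setNames(lam_b, names(tv_blocks)) else numeric(0)

  bh <- baseline_increments(theta, st)
  structure(list(
    coefficients = theta, alpha = alpha, gamma = gamma,
    knots = kn, lambda = lam_named, edf = edf_col,
    var = bread, var_sandwich = var_sand, info = fr$info, penalty = P,
    loglik = fr$loglik, penalized_loglik = fr$penalized_loglik,
    loglik_null = pl_eval(numeric(st$npar), st, want = 0L)$loglik,
    iterations = fr$iterations, converged = fr$converged, flag = fr$flag,
    baseline = bh, blocks = pf$blocks,
    n = st$n, nevent = sum(st$event),
    time = pf$time, event = pf$event, X = pf$X, Z = pf$Z,
    terms = pf$terms, xlevels = pf$xlevels, contrasts = pf$contrasts,
    call = cl), class = "gray_pctvc")
}

# Breslow-type cumulative-hazard increments d_e / S0_e at the distinct
# event times, under the fitted coefficients.
baseline_increments <- function(theta, st) {
  K <- st$K; ptv <- st$ptv
  Eta <- matrix(0, st$n, K)
  if (ptv) Eta <- st$X %*% t(matrix(theta[seq_len(ptv * K)], nrow = K))
  if (st$pf) Eta <- Eta + drop(st$Z %*% theta[ptv * K + seq_len(st$pf)])
  dH <- numeric(length(st$et))
  for (k in seq_len(K)) {
    ek <- which(st$kk == k)
    if (!length(ek)) next
    cw <- cumsum(exp(Eta[st$ord, k]))
    dH[ek] <- st$d[ek] / cw[st$pos[ek]]
  }
  list(time = st$et, hazard = dH, interval = st$kk)
}

#' Effective degrees of freedom of a fitted model
#'
#' Per time-varying column, the trace of its block of `(I + P)^{-1} I`:
#' equal to `K` at `lambda = 0`, decreasing in `lambda`, and tending to 1
#' as `lambda -> Inf`.
#'
#' @param fit a `gray_pctvc` fit.
#' @return Named numeric vector of per-column effective df.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "gray_pctvc"))
  fit$edf
}

#' Evaluate the penalized log partial likelihood of a fit
#'
#' Returns the Efron log partial likelihood at the fitted (or supplied)
#' coefficients minus the first-difference penalty; useful for checking
#' against independent evaluations.
#'
#' @param fit a `gray_pctvc` fit.
#' @param theta optional coefficient vector in the fit's layout.
#' @return Scalar penalized log partial likelihood.
#' @export
penalized_loglik <- function(fit, theta = NULL) {
  stopifnot(inherits(fit, "gray_pctvc"))
  st <- pl_prepare(fit$time, fit$event, fit$X, fit$Z, fit$knots$tau)
  th <- if (is.null(theta)) fit$coefficients else theta
  pl_eval(th, st, want = 0L)$loglik - qform(th, fit$penalty)
}
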