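# Penalized Efron partial-likelihood engine for piecewise-constant
# time-varying coefficient models.
#
# Parameter layout: theta = c(alpha_{1,1..K}, ..., alpha_{ptv,1..K}, gamma),
# where alpha_j is the K-vector of interval levels of time-varying column j
# of X and gamma the coefficients of the time-invariant columns Z.
# Within an event time all subjects share the same coefficient interval, so
# risk-set sums are computed per interval from cumulative sums over subjects
# sorted by decreasing follow-up time; untied event times are fully
# vectorised and tied ones take the exact Efron loop.

interval_index <- function(t, tau) {
  K <- length(tau) - 1L
  pmin.int(pmax.int(findInterval(t, tau, rightmost.closed = TRUE), 1L), K)
}

# symmetric p x p matrix from its packed upper triangle (a <= b, col-major)
expand_sym <- function(v, p, pr) {
  M <- matrix(0, p, p)
  M[cbind(pr[, 1L], pr[, 2L])] <- v
  M[cbind(pr[, 2L], pr[, 1L])] <- v
  M
}

pl_prepare <- function(time, event, X, Z, tau) {
  n <- length(time)
  K <- length(tau) - 1L
  ptv <- ncol(X)
  pf <- ncol(Z)
  p <- ptv + pf
  V <- cbind(X, Z)    # p may be 0 (baseline-only model)
  ord <- order(time, decreasing = TRUE)
  Vs <- V[ord, , drop = FALSE]
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pr <- pr[order(pr[, 2L], pr[, 1L]), , drop = FALSE]
  VVs <- Vs[, pr[, 1L], drop = FALSE] * Vs[, pr[, 2L], drop = FALSE]
  ei <- which(event == 1)
  if (length(ei) == 0L) stop("no events to model")
  et <- sort(unique(time[ei]))
  pos <- vapply(et, function(t) sum(time >= t), integer(1))
  kk <- interval_index(et, tau)
  di <- unname(split(ei, factor(time[ei], levels = et)))
  list(n = n, K = K, ptv = ptv, pf = pf, p = p, npar = ptv * K + pf,
       V = V, Vs = Vs, VVs = VVs, pr = pr, ord = ord,
       et = et, pos = pos, kk = kk, di = di, d = unname(lengths(di)),
       X = X, Z = Z, tau = tau, time = time, event = event)
}

# full-parameter scatter indices for interval k
scatter_idx <- function(st, k) {
  c(if (st$ptv) (seq_len(st$ptv) - 1L) * st$K + k,
    if (st$pf) st$ptv * st$K + seq_len(st$pf))
}

# log partial likelihood (Efron ties) and, for want >= 1/2, its gradient
# and the observed information (-Hessian), all unpenalized.
pl_eval <- function(theta, st, want = 2L) {
  K <- st$K; ptv <- st$ptv; pf <- st$pf; p <- st$p
  Eta <- matrix(0, st$n, K)
  if (ptv) {
    A <- matrix(theta[seq_len(ptv * K)], nrow = K)   # col j = alpha_j
    Eta <- st$X %*% t(A)
  }
  if (pf) Eta <- Eta + drop(st$Z %*% theta[ptv * K + seq_len(pf)])
  if (any(!is.finite(Eta)) || max(Eta) > 500) {
    return(list(loglik = -Inf, grad = NULL, info = NULL))
  }
  ll <- 0
  G <- if (want >= 1L) numeric(st$npar) else NULL
  H <- if (want >= 2L) matrix(0, st$npar, st$npar) else NULL
  for (k in seq_len(K)) {
    ek <- which(st$kk == k)
    if (!length(ek)) next
    wk <- exp(Eta[st$ord, k])
    cw <- cumsum(wk)
    S0 <- cw[st$pos[ek]]
    untied <- st$d[ek] == 1L
    ids1 <- unlist(st$di[ek[untied]], use.names = FALSE)
    if (length(ids1)) {
      ll <- ll + sum(Eta[ids1, k]) - sum(log(S0[untied]))
    }
    g <- numeric(p); Hk <- NULL
    cs1 <- NULL; cs2 <- NULL
    if (want >= 1L) {
      cs1 <- apply(wk * st$Vs, 2L, cumsum)
      if (st$n == 1L) cs1 <- matrix(cs1, nrow = 1L)
      S1 <- cs1[st$pos[ek], , drop = FALSE]
      if (length(ids1)) {
        g <- colSums(st$V[ids1, , drop = FALSE]) -
          colSums(S1[untied, , drop = FALSE] / S0[untied])
      }
      if (want >= 2L) {
        cs2 <- apply(wk * st$VVs, 2L, cumsum)
        if (st$n == 1L) cs2 <- matrix(cs2, nrow = 1L)
        Hk <- matrix(0, p, p)
        if (length(ids1)) {
          S1u <- S1[untied, , drop = FALSE] / S0[untied]
          s2 <- colSums(cs2[st$pos[ek][untied], , drop = FALSE] / S0[untied])
          Hk <- expand_sym(s2, p, st$pr) - crossprod(S1u)
        }
      }
    }
    ## exact Efron treatment of tied event times
    for (j in which(!untied)) {
      e <- ek[j]
      ids <- st$di[[e]]
      d <- st$d[e]
      Vi <- st$V[ids, , drop = FALSE]
      wd <- exp(Eta[ids, k])
      S0D <- sum(wd)
      ll <- ll + sum(Eta[ids, k])
      S0e <- S0[j]
      if (want >= 1L) {
        g <- g + colSums(Vi)
        S1e <- cs1[st$pos[e], ]
        S1D <- colSums(wd * Vi)
        if (want >= 2L) {
          S2e <- cs2[st$pos[e], ]
          S2D <- colSums(wd * (Vi[, st$pr[, 1L], drop = FALSE] *
                                 Vi[, st$pr[, 2L], drop = FALSE]))
        }
      }
      for (r in seq_len(d) - 1L) {
        f <- r / d
        den <- S0e - f * S0D
        ll <- ll - log(den)
        if (want >= 1L) {
          m <- (S1e - f * S1D) / den
          g <- g - m
          if (want >= 2L) {
            Hk <- Hk + expand_sym((S2e - f * S2D) / den, p, st$pr) -
              tcrossprod(m)
          }
        }
      }
    }
    if (want >= 1L) {
      idx <- scatter_idx(st, k)
      G[idx] <- G[idx] + g
      if (want >= 2L) H[idx, idx] <- H[idx, idx] + Hk
    }
  }
  list(loglik = ll, grad = G, info = H)
}

qform <- function(theta, P) {
  if (is.null(P)) 0 else drop(crossprod(theta, P %*% theta)) / 2
}

solve_safe <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    ridge <- 1e-8 * max(abs(diag(A)), 1)
    out <- tryCatch(solve(A + diag(ridge, nrow(A)), b),
                    error = function(e) NULL)
    if (is.null(out)) {
      out <- MASS_ginv(A) %*% b
      if (is.matrix(b)) out else drop(out)
    }
  }
  out
}

# Moore-Penrose inverse via SVD (small matrices only)
MASS_ginv <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L || ncol(A) == 0L) return(matrix(0, ncol(A), nrow(A)))
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Penalized Newton-Raphson with step halving.  P is the (npar x npar)
# penalty matrix (possibly NULL for none); theta0 an optional warm start.
pl_fit <- function(st, P = NULL, theta0 = NULL,
                   control = list(grad_tol = 1e-8, rel_tol = 1e-10,
                                  maxit = 50L, sep_limit = 15)) {
  npar <- st$npar
  if (npar == 0L) {
    ev <- pl_eval(numeric(0), st, want = 0L)
    return(list(theta = numeric(0), loglik = ev$loglik,
                penalized_loglik = ev$loglik, grad = numeric(0),
                info = matrix(0, 0, 0), iterations = 0L,
                converged = TRUE, flag = NULL))
  }
  theta <- if (is.null(theta0)) numeric(npar) else theta0
  ev <- pl_eval(theta, st, want = 2L)
  if (!is.finite(ev$loglik)) { theta <- numeric(npar); ev <- pl_eval(theta, st, 2L) }
  llp <- ev$loglik - qform(theta, P)
  converged <- FALSE
  flag <- NULL
  it <- 0L
  while (it < control$maxit) {
    it <- it + 1L
    gp <- ev$grad - if (is.null(P)) 0 else drop(P %*% theta)
    Ip <- ev$info + if (is.null(P)) 0 else P
    if (max(abs(gp)) < control$grad_tol) { converged <- TRUE; break }
    step <- solve_safe(Ip, gp)
    fac <- 1
    repeat {
      thn <- theta + fac * step
      lln <- pl_eval(thn, st, want = 0L)$loglik - qform(thn, P)
      if (is.finite(lln) && lln >= llp - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { thn <- theta; lln <- llp; break }
    }
    theta <- thn
    ev <- pl_eval(theta, st, want = 2L)
    llp_new <- ev$loglik - qform(theta, P)
    if (max(abs(theta)) > control$sep_limit) {
      flag <- "separation: a coefficient exceeded the search limit while the likelihood was still improving"
      break
    }
    if (abs(llp_new - llp) < control$rel_tol * (abs(llp) + 1e-10)) {
      llp <- llp_new
      gp <- ev$grad - if (is.null(P)) 0 else drop(P %*% theta)
      converged <- TRUE
      break
    }
    llp <- llp_new
  }
  gp <- ev$grad - if (is.null(P)) 0 else drop(P %*% theta)
  if (!converged && is.null(flag) && max(abs(gp)) < 1e-4) converged <- TRUE
  list(theta = theta, loglik = ev$loglik, penalized_loglik = llp,
       grad = ev$grad, info = ev$info, iterations = it,
       converged = converged, flag = flag)
}
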