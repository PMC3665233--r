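#' Knot set for piecewise-constant coefficients
#'
#' A knot set partitions the follow-up axis `[0, T]`, `T` the maximum
#' observed failure time, into `K` intervals `[tau_k, tau_{k+1})` (the last
#' interval closed at `T`).  Interior knots are observed failure times.
#'
#' @param interior strictly increasing interior knots (days); may be empty.
#' @param T maximum observed failure time (days).
#' @return Object of class `knot_set`: list with `K` (number of intervals)
#'   and `tau = c(0, interior, T)`.
#' @export
knot_set <- function(interior, T) {
  interior <- as.numeric(interior)
  if (length(interior) && (any(diff(interior) <= 0) || any(interior <= 0) ||
                           any(interior >= T))) {
    stop("interior knots must be strictly increasing within (0, T)")
  }
  structure(list(K = length(interior) + 1L, tau = c(0, interior, T)),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat("Knot set: K =", x$K, "interval(s); boundaries",
      paste(signif(x$tau, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Place knots at failure-time quantiles
#'
#' Chooses `K - 1` interior knots at observed failure times so that the
#' intervals hold roughly equal numbers of events: the k-th interior knot is
#' the smallest event time with at least `ceiling(D * k / K)` events before
#' it (`D` = total events).  Tied event times are never split across a knot;
#' if ties make some quantile boundaries coincide, duplicated knots are
#' dropped and `K` collapses with a warning.
#'
#' @param x a `survcohort` object or data frame with `time` and `event`.
#' @param K requested number of intervals; `NULL` for the default
#'   `max(2, min(10, ceiling(D / 8)))`, i.e. intervals holding about 8
#'   events each.
#' @return A [knot_set()].
#' @export
place_knots <- function(x, K = NULL) {
  tt <- x$time[x$event == 1]
  if (length(tt) == 0L) stop("no events to model")
  Tmax <- max(tt)
  D <- length(tt)
  if (is.null(K)) K <- max(2L, min(10L, as.integer(ceiling(D / 8))))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) return(knot_set(numeric(0), Tmax))
  et <- sort(unique(tt))
  if (K > length(et)) {
    stop("K = ", K, " exceeds the ", length(et),
         " distinct event times; use K <= ", length(et))
  }
  nbefore <- vapply(et, function(t) sum(tt < t), integer(1))
  interior <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    need <- ceiling(D * k / K)
    ok <- which(nbefore >= need)
    interior[k] <- if (length(ok)) et[ok[1L]] else NA_real_
  }
  interior <- interior[!is.na(interior) & interior < Tmax]
  interior <- unique(interior)
  if (length(interior) < K - 1L) {
    warning("tied failure times cannot be split: K collapsed from ", K,
            " to ", length(interior) + 1L)
  }
  knot_set(interior, Tmax)
}

#' First-difference roughness penalty
#'
#' Value of the penalty `(lambda / 2) * sum_{k=2}^{K} (alpha_k -
#' alpha_{k-1})^2` that shrinks the jumps of a piecewise-constant
#' coefficient between adjacent intervals.  Zero when all levels are equal,
#' when `K = 1`, or when `lambda = 0`.
#'
#' @param alpha numeric vector of interval levels (length `K`).
#' @param lambda nonnegative smoothing parameter.
#' @return Scalar penalty value.
#' @export
penalty_value <- function(alpha, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (length(alpha) < 2L) return(0)
  lambda / 2 * sum(diff(alpha)^2)
}

# K x K penalty kernel D'D for the first-difference penalty
penalty_kernel <- function(K) {
  if (K < 2L) return(matrix(0, K, K))
  D <- diff(diag(K))
  crossprod(D)
}

# full penalty matrix over the engine layout, lambda per tv column
penalty_matrix <- function(ptv, K, pf, lambda) {
  npar <- ptv * K + pf
  P <- matrix(0, npar, npar)
  if (ptv && K > 1L) {
    DtD <- penalty_kernel(K)
    for (j in seq_len(ptv)) {
      idx <- (j - 1L) * K + seq_len(K)
      P[idx, idx] <- lambda[j] * DtD
    }
  }
  P
}
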