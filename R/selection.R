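# Two-stage covariate selection: univariable screen with the
# time-varying-coefficient model, then forward selection on the
# overall-effect test in the growing multivariable fit.

surv_formula <- function(time, event, terms) {
  stats::as.formula(paste0("survival::Surv(`", time, "`, `", event, "`) ~ ",
                           paste(terms, collapse = " + ")),
                    env = globalenv())
}

block_p <- function(fit, candidate, rule = c("min", "joint")) {
  rule <- match.arg(rule)
  cols <- NULL
  for (b in fit$blocks) if (b$label == candidate) cols <- b$cols
  if (is.null(cols)) stop("candidate not in fit: ", candidate)
  if (rule == "min") {
    min(vapply(cols, function(cl) test_overall(fit, cl)$p.value, 0))
  } else {
    # joint Wald over the whole block
    idx <- unlist(lapply(cols, function(cl) {
      K <- fit$knots$K
      if (cl %in% names(fit$alpha)) {
        (match(cl, names(fit$alpha)) - 1L) * K + seq_len(K)
      } else length(fit$alpha) * K + match(cl, names(fit$gamma))
    }))
    a <- fit$coefficients[idx]
    stat <- wald_quadform(a, fit$var[idx, idx, drop = FALSE])
    df <- sum(vapply(cols, function(cl) {
      if (cl %in% names(fit$edf)) fit$edf[[cl]] else 1
    }, 0))
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
}

#' Univariable screen with time-varying-coefficient fits
#'
#' Fits each candidate covariate alone as a `tv()` term with the given
#' target degrees of freedom and keeps candidates whose overall-effect
#' p-value is at or below `alpha` (default 0.15).  A factor candidate is
#' one block: its p-value is the minimum over its indicator columns
#' (`block_rule = "min"`, the default) or a joint Wald test
#' (`block_rule = "joint"`).  Candidates whose fit fails are excluded and
#' logged with the reason.
#'
#' @param data a `survcohort` or data frame.
#' @param candidates character vector of covariate column names.
#' @param time,event names of the time and event columns.
#' @param alpha screening significance level.
#' @param df target effective degrees of freedom per candidate.
#' @param K number of knot intervals (`NULL` for the default rule).
#' @param block_rule how a factor block's p-value is formed.
#' @return Object of class `screen_result`: list with `passed` (character)
#'   and `trace` (data frame of candidate, p-value, decision, note).
#' @export
univariable_screen <- function(data, candidates, time = "time",
                               event = "event", alpha = 0.15, df = 4,
                               K = NULL, block_rule = c("min", "joint")) {
  block_rule <- match.arg(block_rule)
  data <- as.data.frame(data)
  rows <- list()
  passed <- character(0)
  for (nm in candidates) {
    p <- NA_real_
    note <- ""
    ok <- FALSE
    res <- tryCatch({
      f <- suppressWarnings(
        pctvc(surv_formula(time, event, paste0("tv(`", nm, "`)")),
              data, df = df, K = K))
      if (!f$converged) stop(f$flag %||% "did not converge")
      p <- block_p(f, nm, block_rule)
      ok <- p <= alpha
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.character(res) && is.na(p)) note <- res
    rows[[nm]] <- data.frame(candidate = nm, stage = "univariable",
                             p = p, decision = if (ok) "pass" else "drop",
                             note = note)
    if (ok) passed <- c(passed, nm)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  structure(list(passed = passed, trace = trace, alpha = alpha, df = df),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Univariable screen at alpha =", x$alpha, "(df =", x$df, "):",
      length(x$passed), "of", nrow(x$trace), "candidates pass\n")
  print(x$trace, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Forward selection on the overall-effect test
#'
#' Starting from the empty model, repeatedly fits the current model plus
#' each remaining candidate (all as `tv()` terms), adds the candidate
#' block with the smallest overall-effect p-value if it is at or below
#' `entry_alpha`, and stops otherwise.  Blocks enter as units; a candidate
#' whose fit fails at a step is skipped for that step and logged.
#'
#' @inheritParams univariable_screen
#' @param entry_alpha entry p-value threshold (default 0.05).
#' @return Object of class `forward_result`: list with `selected`
#'   (character, in entry order), `fit` (final `gray_pctvc`, or `NULL` if
#'   nothing entered) and `trace`.
#' @export
forward_select <- function(data, candidates, time = "time", event = "event",
                           entry_alpha = 0.05, df = 4, K = NULL,
                           block_rule = c("min", "joint")) {
  block_rule <- match.arg(block_rule)
  data <- as.data.frame(data)
  selected <- character(0)
  remaining <- candidates
  trace <- list()
  step <- 0L
  final_fit <- NULL
  while (length(remaining)) {
    step <- step + 1L
    pvals <- stats::setNames(rep(NA_real_, length(remaining)), remaining)
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      nm <- remaining[i]
      msg <- tryCatch({
        f <- suppressWarnings(
          pctvc(surv_formula(time, event,
                             paste0("tv(`", c(selected, nm), "`)")),
                data, df = df, K = K))
        if (!f$converged) stop(f$flag %||% "did not converge")
        pvals[nm] <- block_p(f, nm, block_rule)
        fits[[i]] <- f
        NULL
      }, error = function(e) conditionMessage(e))
      trace[[length(trace) + 1L]] <- data.frame(
        candidate = nm, stage = paste0("forward_step", step),
        p = pvals[nm],
        decision = "evaluated",
        note = if (is.null(msg)) "" else msg)
    }
    if (all(is.na(pvals))) break
    best <- which.min(pvals)
    if (pvals[best] <= entry_alpha) {
      selected <- c(selected, remaining[best])
      final_fit <- fits[[best]]
      trace[[length(trace) + 1L]] <- data.frame(
        candidate = remaining[best], stage = paste0("forward_step", step),
        p = pvals[best], decision = "enter", note = "")
      remaining <- remaining[-best]
    } else break
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(selected = selected, fit = final_fit, trace = trace,
                 entry_alpha = entry_alpha),
            class = "forward_result")
}

#' @export
print.forward_result <- function(x, ...) {
  cat("Forward selection (entry alpha =", x$entry_alpha, "): selected",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else
        "nothing", "\n")
  invisible(x)
}

#' Check two-way interactions of a fitted model
#'
#' For every unordered pair of covariate blocks in the final model, adds
#' the pairwise products of their design columns as time-invariant terms
#' (one pair at a time, model otherwise unchanged) and reports a joint
#' Wald p-value for the added terms.  The knots and smoothing parameters
#' of the base fit are reused.
#'
#' @param fit the final `gray_pctvc` fit.
#' @param data the data the model was fitted to.
#' @param alpha flagging level for the report.
#' @return Data frame with one row per pair (`pair`, `statistic`, `df`,
#'   `p`, `flagged`); zero rows when the model has fewer than two blocks.
#' @export
interaction_check <- function(fit, data, alpha = 0.05) {
  stopifnot(inherits(fit, "gray_pctvc"))
  blocks <- fit$blocks
  if (length(blocks) < 2L) {
    return(data.frame(pair = character(0), statistic = numeric(0),
                      df = numeric(0), p = numeric(0),
                      flagged = logical(0)))
  }
  data <- as.data.frame(data)
  mm <- design_for(fit, data)
  labs <- unique(vapply(blocks, `[[`, "", "label"))
  combs <- utils::combn(labs, 2L, simplify = FALSE)
  rows <- list()
  for (pp in combs) {
    ca <- blocks[[pp[1L]]]$cols
    cb <- blocks[[pp[2L]]]$cols
    prods <- list()
    for (a in ca) for (b in cb) {
      prods[[paste0(".ia_", a, "_x_", b)]] <- mm[, a] * mm[, b]
    }
    d2 <- cbind(data, as.data.frame(prods))
    base_terms <- attr(fit$terms, "term.labels")
    form <- surv_formula(all.vars(fit$terms)[1L], all.vars(fit$terms)[2L],
                         c(base_terms, paste0("`", names(prods), "`")))
    res <- tryCatch({
      f2 <- pctvc(form, d2, lambda = if (length(fit$lambda)) fit$lambda
                  else NULL, knots = fit$knots)
      idx <- length(f2$alpha) * f2$knots$K +
        match(names(prods), names(f2$gamma))
      a <- f2$coefficients[idx]
      stat <- wald_quadform(a, f2$var[idx, idx, drop = FALSE])
      df <- length(idx)
      data.frame(pair = paste(pp, collapse = ":"), statistic = stat,
                 df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
    }, error = function(e) {
      data.frame(pair = paste(pp, collapse = ":"), statistic = NA_real_,
                 df = NA_real_, p = NA_real_)
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$p) & out$p <= alpha
  rownames(out) <- NULL
  out
}
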