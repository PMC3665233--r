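#' Construct a right-censored survival cohort
#'
#' Normalises a data frame of one-row-per-subject survival records into a
#' `survcohort` object: positive follow-up times in days, a 0/1 event
#' indicator (1 = death), unique subject identifiers, and covariate columns
#' that are either numeric or factor.  Missing covariate values are kept
#' (masked as `NA`), never dropped; use [complete_cases()] for an explicit
#' complete-case extraction.
#'
#' @param data data frame with one row per subject.
#' @param time name of the follow-up time column (days).
#' @param event name of the 0/1 event indicator column.
#' @param id name of the subject identifier column, or `NULL` to use row
#'   numbers.
#' @param categorical character vector of covariate columns to treat as
#'   categorical; levels are registered in first-seen order.  Character
#'   columns are always treated as categorical.
#' @return An object of class `survcohort`: a data frame with columns
#'   `id`, `time`, `event` followed by the covariates, with attributes
#'   recording the column roles.
#' @seealso [read_cohort()], [complete_cases()], [encode_categoricals()]
#' @export
survival_cohort <- function(data, time = "time", event = "event",
                            id = NULL, categorical = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("no records")
  for (col in c(time, event, id, categorical)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  tt <- as.numeric(data[[time]])
  ev <- data[[event]]
  if (!all(ev %in% c(0, 1, NA))) {
    bad <- which(!(ev %in% c(0, 1)))[1L]
    stop("unknown event code in row ", bad, ": ", ev[bad])
  }
  if (anyNA(ev) || anyNA(tt)) {
    bad <- which(is.na(ev) | is.na(tt))[1L]
    stop("missing time or event in row ", bad)
  }
  ev <- as.integer(ev)
  drop <- which(tt <= 0)
  if (length(drop)) {
    warning("rejected ", length(drop), " row(s) with nonpositive time: rows ",
            paste(utils::head(drop, 10L), collapse = ", "))
    data <- data[-drop, , drop = FALSE]
    tt <- tt[-drop]; ev <- ev[-drop]
    if (nrow(data) == 0L) stop("no records")
  }
  ids <- if (is.null(id)) seq_len(nrow(data)) else data[[id]]
  if (anyDuplicated(ids)) stop("subject ids are not unique")
  covar_names <- setdiff(names(data), c(time, event, id))
  covs <- data[covar_names]
  for (nm in covar_names) {
    x <- covs[[nm]]
    if (nm %in% categorical || is.character(x) || is.logical(x)) {
      lev <- unique(x[!is.na(x)])
      covs[[nm]] <- factor(x, levels = if (is.factor(x)) levels(x) else lev)
    } else if (!is.numeric(x) && !is.factor(x)) {
      stop("covariate ", nm, " is neither numeric nor categorical")
    }
  }
  out <- data.frame(id = ids, time = tt, event = ev, check.names = FALSE)
  out <- cbind(out, covs)
  structure(out, class = c("survcohort", "data.frame"),
            covariates = covar_names)
}

#' Read a delimited survival cohort file
#'
#' Reads a CSV or TSV file with a header row and builds a [survival_cohort()].
#' The delimiter is taken from the file extension (`.tsv`/`.txt` are
#' tab-separated, everything else comma-separated) unless `sep` is given.
#'
#' @inheritParams survival_cohort
#' @param path path to the delimited file.
#' @param sep field separator, or `NULL` to infer from the extension.
#' @return A `survcohort` object.
#' @examples
#' path <- system.file("extdata", "ab_recipients.csv", package = "graytvc")
#' ab <- read_cohort(path)
#' nrow(ab); sum(ab$event)
#' @export
read_cohort <- function(path, time = "time", event = "event", id = NULL,
                        categorical = NULL, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no records")
  survival_cohort(df, time = time, event = event, id = id,
                  categorical = categorical)
}

#' Write a survival cohort to a delimited file
#'
#' @param x a `survcohort` object.
#' @param path output path; extension selects the delimiter as in
#'   [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.survcohort <- function(x, ...) {
  cat("Right-censored cohort: ", nrow(x), " subjects, ",
      sum(x$event), " events (",
      sprintf("%.1f%%", 100 * mean(x$event)), ")\n", sep = "")
  cat("Follow-up (days): median ", stats::median(x$time),
      ", max ", max(x$time), "\n", sep = "")
  covs <- attr(x, "covariates")
  if (length(covs)) cat("Covariates:", paste(covs, collapse = ", "), "\n")
  nmiss <- sum(is.na(x[covs]))
  if (nmiss) cat("Missing covariate cells:", nmiss, "\n")
  invisible(x)
}

#' Extract complete cases from a cohort
#'
#' Drops subjects with any missing covariate cell.  This is the explicit
#' complete-case step; construction and I/O never drop masked values.
#'
#' @param x a `survcohort` object.
#' @return A `survcohort` with no missing covariate cells.
#' @export
complete_cases <- function(x) {
  covs <- attr(x, "covariates")
  keep <- stats::complete.cases(as.data.frame(x)[covs])
  out <- x[keep, , drop = FALSE]
  structure(out, class = class(x), covariates = covs)
}

#' Expand categorical covariates into reference-coded indicators
#'
#' Replaces each L-level categorical covariate by L-1 0/1 indicator columns
#' (one per non-reference level, named `variable.level`), recording block
#' membership so that selection and tests can treat the original variable as
#' a unit.
#'
#' @param x a `survcohort` object.
#' @param reference named character vector giving the reference level per
#'   categorical variable; defaults to each variable's first registered
#'   level.
#' @return A `survcohort` whose categorical covariates are replaced by
#'   indicator columns, with attribute `blocks`: a named list mapping each
#'   original variable to its indicator column names.
#' @export
encode_categoricals <- function(x, reference = NULL) {
  covs <- attr(x, "covariates")
  df <- as.data.frame(x)
  blocks <- list()
  out_cov <- character(0)
  newcols <- list()
  for (nm in covs) {
    v <- df[[nm]]
    if (!is.factor(v)) {
      newcols[[nm]] <- v
      out_cov <- c(out_cov, nm)
      blocks[[nm]] <- nm
      next
    }
    lev <- levels(v)
    ref <- if (!is.null(reference) && nm %in% names(reference)) {
      reference[[nm]]
    } else lev[1L]
    if (!ref %in% lev) stop("reference level ", ref, " not found for ", nm)
    keep <- setdiff(lev, ref)
    if (length(keep) == 0L) {
      warning("covariate ", nm, " has no variation; no indicators created")
      blocks[[nm]] <- character(0)
      next
    }
    cols <- character(0)
    for (lv in keep) {
      cn <- paste0(nm, ".", lv)
      ind <- as.integer(v == lv)
      ind[is.na(v)] <- NA_integer_
      newcols[[cn]] <- ind
      cols <- c(cols, cn)
    }
    blocks[[nm]] <- cols
    out_cov <- c(out_cov, cols)
  }
  out <- data.frame(id = df$id, time = df$time, event = df$event,
                    check.names = FALSE)
  for (nm in names(newcols)) out[[nm]] <- newcols[[nm]]
  structure(out, class = c("survcohort", "data.frame"),
            covariates = out_cov, blocks = blocks)
}

#' Risk-set structure at the distinct event times
#'
#' Computes, for each distinct event time, the risk set (subjects with
#' follow-up time at or beyond it; a subject censored on the same day is
#' still at risk), the death set, and the tie count.  Censored-only times
#' never appear.
#'
#' @param x a `survcohort` object or a data frame with `time` and `event`.
#' @return An object of class `risk_structure`: list with `event_times`
#'   (ascending), `d` (tie counts), `risk_sets` and `death_sets` (lists of
#'   row indices into `x`).
#' @export
build_risk_structure <- function(x) {
  tt <- x$time; ev <- x$event
  if (sum(ev) == 0L) stop("no events to model")
  et <- sort(unique(tt[ev == 1]))
  rs <- lapply(et, function(t) which(tt >= t))
  ds <- lapply(et, function(t) which(tt == t & ev == 1))
  structure(list(event_times = et, d = lengths(ds),
                 risk_sets = rs, death_sets = ds),
            class = "risk_structure")
}

#' @export
print.risk_structure <- function(x, ...) {
  cat("Risk structure: ", length(x$event_times), " distinct event times, ",
      sum(x$d), " events\n", sep = "")
  invisible(x)
}

#' Split a cohort into knot-interval episodes
#'
#' Counting-process representation: each subject contributes one
#' `(start, stop]` episode per knot interval overlapping its follow-up,
#' with the event flag on the final episode only.  The partial likelihood
#' of any piecewise-constant coefficient model evaluated on the episodes
#' equals direct evaluation on the original records.
#'
#' @param x a `survcohort` object.
#' @param knots a [knot_set()] (or the numeric vector of its boundaries
#'   `c(0, interior..., T)`).
#' @return Data frame with columns `id`, `start`, `stop`, `event`,
#'   `interval`, followed by the subject's covariates.
#' @export
split_episodes <- function(x, knots) {
  tau <- if (inherits(knots, "knot_set")) knots$tau else as.numeric(knots)
  cuts <- tau[-c(1L, length(tau))]           # interior knots only
  covs <- attr(x, "covariates")
  df <- as.data.frame(x)
  n <- nrow(df)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- df$time[i]
    b <- c(0, cuts[cuts < ti], ti)
    m <- length(b) - 1L
    pieces[[i]] <- data.frame(
      id = rep(df$id[i], m),
      start = b[-length(b)],
      stop = b[-1L],
      event = c(rep(0L, m - 1L), df$event[i]),
      interval = findInterval(b[-length(b)], tau, rightmost.closed = TRUE),
      check.names = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  idx <- rep(seq_len(n), vapply(pieces, nrow, 0L))
  cbind(out, df[idx, covs, drop = FALSE], row.names = NULL)
}
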