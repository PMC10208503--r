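#' Partial correlation via residual correlation
#'
#' Correlation of the least-squares residuals of `x` and `y` each regressed
#' on the conditioning set (with intercept), over complete cases.  With an
#' empty conditioning set this is the Pearson correlation.  A sex (or other
#' two-level categorical) column is coded 0/1 automatically.
#'
#' @param data data.frame.
#' @param x,y column names.
#' @param given character vector of conditioning columns (default empty).
#' @return list with `r` (partial correlation) and `n` (complete cases used).
#' @export
partial_correlation <- function(data, x, y, given = character()) {
  vars <- c(x, y, given)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  m <- data[vars]
  for (v in vars) m[[v]] <- to_numeric_col(m[[v]], v)
  cc <- stats::complete.cases(m)
  n <- sum(cc)
  if (n < length(given) + 3L) {
    stop("insufficient complete cases (", n, ") for {",
         paste(vars, collapse = ", "), "}")
  }
  m <- m[cc, , drop = FALSE]
  if (length(given) == 0L) {
    return(list(r = stats::cor(m[[x]], m[[y]]), n = n))
  }
  z <- cbind(1, as.matrix(m[given]))
  qz <- qr(z)
  if (qz$rank < ncol(z)) {
    stop("collinear conditioning set: {", paste(given, collapse = ", "), "}")
  }
  rx <- stats::resid(stats::lm.fit(z, m[[x]]))
  ry <- stats::resid(stats::lm.fit(z, m[[y]]))
  list(r = stats::cor(rx, ry), n = n)
}

# 0/1-code two-level factors/characters/logicals; pass numerics through.
to_numeric_col <- function(v, name) {
  if (is.numeric(v)) return(v)
  if (is.logical(v)) return(as.numeric(v))
  lev <- sort(unique(v[!is.na(v)]))
  if (length(lev) > 2L) {
    stop("column '", name, "' is categorical with >2 levels; ",
         "recode before correlation analysis")
  }
  as.numeric(match(v, lev) - 1L)
}

#' Test the plausibility of a causal model against data
#'
#' Evaluates every conditional independency implied by the DAG (from
#' [implied_independencies()]) as a partial correlation in the data.  The
#' model is judged plausible when every implied-independence partial
#' correlation is inside the cutoff (conventionally +/- 0.3).
#'
#' @param dag a [causal_dag()].
#' @param data data.frame whose columns cover the DAG's observed variables
#'   (directly or via `var_map`).
#' @param cutoff absolute partial-correlation threshold, in (0, 1) —
#'   `0.3` by convention.  A cutoff of 0 fails any finite sample.
#' @param var_map named character vector, DAG variable -> data column; DAG
#'   names present verbatim in `data` need no entry.
#' @return object of class `plausibility_report`: data.frame `implications`
#'   (x, y, given, n, r, pass, evaluable) sorted by |r| descending,
#'   `max_abs_r`, `cutoff`, `verdict` (`"pass"`/`"fail"`).  Implications
#'   with too few complete cases are flagged unevaluable, not fatal.
#' @export
test_model_plausibility <- function(dag, data, cutoff = 0.3,
                                    var_map = NULL) {
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  lookup <- function(v) {
    if (!is.null(var_map) && v %in% names(var_map)) var_map[[v]] else v
  }
  need <- vapply(dag$observed, lookup, character(1L))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("DAG variable(s) not mappable to data columns: ",
         paste(miss, collapse = ", "))
  }
  imps <- implied_independencies(dag)
  rows <- lapply(imps, function(s) {
    res <- tryCatch(
      partial_correlation(data, lookup(s$x), lookup(s$y),
                          vapply(s$given, lookup, character(1L))),
      error = function(e) NULL)
    data.frame(
      x = s$x, y = s$y,
      given = paste(s$given, collapse = ", "),
      n = if (is.null(res)) NA_integer_ else res$n,
      r = if (is.null(res)) NA_real_ else res$r,
      evaluable = !is.null(res),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(x = character(), y = character(), given = character(),
                      n = integer(), r = numeric(), evaluable = logical())
  }
  tab$pass <- !is.na(tab$r) & abs(tab$r) < cutoff
  tab <- tab[order(-abs(tab$r), tab$x, tab$y), , drop = FALSE]
  rownames(tab) <- NULL
  max_abs_r <- if (any(tab$evaluable)) max(abs(tab$r), na.rm = TRUE) else NA_real_
  verdict <- if (nrow(tab) == 0L || (all(tab$pass[tab$evaluable]) &&
                                     !is.na(max_abs_r) && max_abs_r < cutoff)) {
    "pass"
  } else {
    "fail"
  }
  if (nrow(tab) > 0L && !all(tab$evaluable)) verdict <- verdict  # flagged, not fatal
  structure(list(implications = tab, max_abs_r = max_abs_r,
                 cutoff = cutoff, verdict = verdict),
            class = "plausibility_report")
}

#' @export
print.plausibility_report <- function(x, ...) {
  cat("Causal-model plausibility report (cutoff |r| < ", x$cutoff, ")\n",
      sep = "")
  t <- x$implications
  if (!nrow(t)) {
    cat("no testable implications\n")
  } else {
    disp <- data.frame(
      implication = paste0(t$x, " _||_ ", t$y,
                           ifelse(nzchar(t$given), paste0(" | ", t$given), "")),
      n = t$n, r = round(t$r, 4),
      status = ifelse(!t$evaluable, "unevaluable",
                      ifelse(t$pass, "pass", "FAIL")))
    print(disp, row.names = FALSE)
  }
  cat("max |r| =", format(x$max_abs_r, digits = 4), "-> verdict:",
      toupper(x$verdict), "\n")
  invisible(x)
}

#' Serialize a plausibility report to JSON
#'
#' @param report a [test_model_plausibility()] result.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @export
plausibility_json <- function(report, path = NULL) {
  obj <- list(cutoff = report$cutoff, max_abs_r = report$max_abs_r,
              verdict = report$verdict, implications = report$implications)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
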