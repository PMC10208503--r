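#' Accumulated local effects curve
#'
#' First-order ALE of one factor on the model response: bin edges at the
#' factor's sample quantiles; within each bin, the prediction difference
#' between the upper and the lower edge (all other columns held at the
#' row's values) is averaged; the per-bin averages are accumulated and the
#' curve is centered so its interpolated value has (count-weighted) mean
#' zero over the sample.  Because the local differences are taken within
#' the factor's own data neighbourhood, the curve is unbiased under
#' correlated predictors, unlike partial dependence.
#'
#' @param predict_fn function taking a predictor table and returning a
#'   numeric vector of predictions (one per row).  It may also return a
#'   draws-by-rows matrix, in which case per-draw curves are retained.
#' @param data predictor table; rows with a missing factor value are
#'   dropped for this curve (other-column missingness is the model's
#'   business).
#' @param factor name of the (numeric) factor column.
#' @param bins target number of quantile bins K (default 40); reduced when
#'   the factor has fewer distinct values, and duplicate quantile edges are
#'   merged.
#' @return object of class `ale_curve`: `factor`, `edges` (length K'+1),
#'   `effect` (centered accumulated effect at each edge, response units),
#'   `counts` (per-bin), and optionally `draws` (per-draw curve matrix).
#' @export
compute_ale <- function(predict_fn, data, factor, bins = 40L) {
  if (bins < 2L) stop("need at least 2 bins")
  if (!factor %in% names(data)) stop("unknown factor column: ", factor)
  xv <- data[[factor]]
  if (!is.numeric(xv)) stop("factor column must be numeric: ", factor)
  keep <- !is.na(xv)
  data <- data[keep, , drop = FALSE]
  xv <- xv[keep]
  ux <- sort(unique(xv))
  if (length(ux) < 3L) stop("factor '", factor, "' has too few distinct values")
  k <- min(as.integer(bins), length(ux) - 1L)
  edges <- unique(stats::quantile(xv, probs = seq(0, 1, length.out = k + 1L),
                                  names = FALSE, type = 7L))
  k <- length(edges) - 1L
  bin <- findInterval(xv, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = k)

  lo <- data; lo[[factor]] <- edges[bin]
  hi <- data; hi[[factor]] <- edges[bin + 1L]
  p_lo <- predict_fn(lo)
  p_hi <- predict_fn(hi)

  finalize_curve <- function(dlo, dhi) {
    d <- dhi - dlo
    avg <- vapply(seq_len(k), function(b) {
      if (counts[b] == 0L) 0 else mean(d[bin == b])
    }, numeric(1L))
    eff <- c(0, cumsum(avg))
    center <- mean(stats::approx(edges, eff, xout = xv, rule = 2L)$y)
    eff - center
  }

  if (is.matrix(p_lo)) {
    nd <- nrow(p_lo)
    draw_curves <- matrix(NA_real_, nd, k + 1L)
    for (d in seq_len(nd)) {
      draw_curves[d, ] <- finalize_curve(p_lo[d, ], p_hi[d, ])
    }
    effect <- finalize_curve(colMeans(p_lo), colMeans(p_hi))
  } else {
    draw_curves <- NULL
    effect <- finalize_curve(p_lo, p_hi)
  }
  structure(list(factor = factor, edges = edges, effect = effect,
                 counts = counts, draws = draw_curves, x_sample = xv),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat("ALE curve for '", x$factor, "': ", length(x$counts), " bins, effect ",
      "range ", format(diff(range(x$effect)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' ALE curve with an uncertainty band
#'
#' Default (`method = "posterior"`): the ALE curve is recomputed for every
#' posterior draw of the sum-of-trees model and the band is the pointwise
#' 2.5/97.5 percentile envelope — cheap and honest under the model.
#' `method = "bootstrap"` instead resamples rows with replacement, refits
#' the model and recomputes the curve B times; it is costly (B refits) and
#' off by default.
#'
#' @param model a [bart()] fit with at least 20 posterior draws.
#' @param data predictor table used for the curve.
#' @param factor factor column name.
#' @param bins quantile bins (default 40).
#' @param level interval level (default 0.95).
#' @param method `"posterior"` or `"bootstrap"`.
#' @param B bootstrap replicates (bootstrap method only).
#' @return an `ale_curve` with extra elements `lower` and `upper`.
#' @export
ale_uncertainty <- function(model, data, factor, bins = 40L, level = 0.95,
                            method = c("posterior", "bootstrap"), B = 50L) {
  method <- match.arg(method)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (method == "posterior") {
    if (length(model$sigma) < 20L) {
      stop("fewer than 20 posterior draws; run a longer chain")
    }
    curve <- compute_ale(function(nd) predict(model, nd, type = "draws"),
                         data, factor, bins)
    qs <- apply(curve$draws, 2L, stats::quantile, probs = probs, names = FALSE)
    curve$lower <- qs[1L, ]
    curve$upper <- qs[2L, ]
    return(curve)
  }
  # nonparametric bootstrap: resample rows, refit, recompute
  curve <- compute_ale(function(nd) predict(model, nd), data, factor, bins)
  boot <- matrix(NA_real_, B, length(curve$edges))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    db <- data[idx, , drop = FALSE]
    yb <- predict(model, db) +
      stats::rnorm(nrow(db), 0, mean(model$sigma))
    fb <- bart(db, yb, config = model$config)
    cb <- compute_ale(function(nd) predict(fb, nd), data, factor, bins)
    boot[b, ] <- stats::approx(cb$edges, cb$effect, xout = curve$edges,
                               rule = 2L)$y
  }
  qs <- apply(boot, 2L, stats::quantile, probs = probs, names = FALSE)
  curve$lower <- qs[1L, ]
  curve$upper <- qs[2L, ]
  curve
}

#' Effect size: curve range over the middle 95% of the sample
#'
#' The effect size of a factor is the range (max minus min) of its ALE
#' curve restricted to the factor's central sample window, between the
#' 2.5th and 97.5th percentiles — the "middle 95th percentile" of the
#' sample, so extreme tails do not inflate the effect.  The piecewise-linear
#' curve is evaluated at the window endpoints and every knot inside the
#' window.  When the curve carries per-draw replicates an interval for the
#' range is computed from them.
#'
#' @param curve an [compute_ale()] result.
#' @param factor_values sample of factor values defining the window
#'   (defaults to the sample stored in the curve).
#' @param level interval level for the per-draw ranges.
#' @return object of class `effect_size`: `factor`, `window`, `effect`
#'   (watts when the response is power), optional `lower`/`upper`.
#' @export
effect_size <- function(curve, factor_values = curve$x_sample,
                        level = 0.95) {
  if (is.null(factor_values)) stop("no factor sample available")
  w <- stats::quantile(factor_values, c(0.025, 0.975), names = FALSE)
  if (diff(w) <= 0) stop("middle-95% window collapses; factor is ",
                         "near-constant")
  range_on <- function(edges, eff) {
    xs <- c(w, edges[edges > w[1L] & edges < w[2L]])
    ys <- stats::approx(edges, eff, xout = xs, rule = 2L)$y
    max(ys) - min(ys)
  }
  eff <- range_on(curve$edges, curve$effect)
  out <- list(factor = curve$factor, window = w, effect = eff)
  if (!is.null(curve$draws)) {
    rr <- apply(curve$draws, 1L, function(e) range_on(curve$edges, e))
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qi <- stats::quantile(rr, probs, names = FALSE)
    out$lower <- qi[1L]; out$upper <- qi[2L]
  }
  structure(out, class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat("effect of '", x$factor, "' over [",
      format(x$window[1L], digits = 3), ", ",
      format(x$window[2L], digits = 3), "]: ",
      format(x$effect, digits = 4), sep = "")
  if (!is.null(x$lower)) {
    cat(" (", format(x$lower, digits = 4), ", ",
        format(x$upper, digits = 4), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Export ALE curves as a tidy table
#'
#' @param curves list of `ale_curve` objects (possibly with bands).
#' @param path optional CSV file to write.
#' @return data.frame with columns factor, edge, effect, lo, hi, n.
#' @export
ale_table <- function(curves, path = NULL) {
  rows <- lapply(curves, function(cv) {
    k <- length(cv$edges)
    data.frame(factor = cv$factor, edge = cv$edges, effect = cv$effect,
               lo = if (is.null(cv$lower)) NA_real_ else cv$lower,
               hi = if (is.null(cv$upper)) NA_real_ else cv$upper,
               n = c(cv$counts, NA_integer_)[c(seq_len(k - 1L), k - 1L)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Plot an ALE curve
#'
#' Base-graphics rendering with the uncertainty band (when present) and a
#' rug of the factor sample.
#'
#' @param x an `ale_curve`.
#' @param ylab,main usual graphics overrides.
#' @param ... passed to [plot()].
#' @export
plot.ale_curve <- function(x, ylab = "accumulated local effect (W)",
                           main = x$factor, ...) {
  yl <- range(c(x$effect, x$lower, x$upper), na.rm = TRUE)
  plot(x$edges, x$effect, type = "n", xlab = x$factor, ylab = ylab,
       main = main, ylim = yl, ...)
  if (!is.null(x$lower)) {
    graphics::polygon(c(x$edges, rev(x$edges)), c(x$lower, rev(x$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  graphics::lines(x$edges, x$effect, lwd = 2, col = "steelblue4")
  if (!is.null(x$x_sample)) graphics::rug(x$x_sample)
  invisible(x)
}
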