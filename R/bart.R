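#' BART configuration
#'
#' Collects the hyperparameters of the sum-of-trees model.  `num_trees` is
#' the number of trees m; `k` scales the leaf prior (leaf SD = 0.5/(k*sqrt(m))
#' on the response rescaled to [-0.5, 0.5], so larger k shrinks individual
#' trees harder); `nu` and `q` calibrate the scaled-inverse-chi-squared
#' noise prior so that a data-based sigma estimate sits at its q-th
#' quantile; `alpha`/`beta` set the tree-depth prior
#' P(nonterminal at depth d) = alpha*(1+d)^(-beta).
#'
#' @param num_trees number of trees (m >= 1).
#' @param k leaf prior scale (> 0).
#' @param nu,q noise prior degrees of freedom (> 0) and quantile in (0,1).
#' @param alpha,beta tree structure prior parameters.
#' @param n_burn,n_draw burn-in and retained posterior draws.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param use_missing_data route missing predictor values with per-split
#'   direction flags (missingness incorporated in attributes).
#' @return list of class `bart_config`.
#' @export
bart_config <- function(num_trees = 50L, k = 2, nu = 3, q = 0.9,
                        alpha = 0.95, beta = 2, n_burn = 1000L,
                        n_draw = 1000L, seed = NULL,
                        use_missing_data = FALSE) {
  stopifnot(num_trees >= 1L, k > 0, nu > 0, q > 0, q < 1,
            alpha > 0, alpha < 1, beta >= 0, n_burn >= 0L, n_draw >= 1L)
  structure(list(num_trees = as.integer(num_trees), k = k, nu = nu, q = q,
                 alpha = alpha, beta = beta, n_burn = as.integer(n_burn),
                 n_draw = as.integer(n_draw), seed = seed,
                 use_missing_data = isTRUE(use_missing_data)),
            class = "bart_config")
}

# Encode a predictor table to a numeric matrix, preserving NA.  Two-level
# categoricals become a single 0/1 column; multi-level ones are one-hot.
# `meta` (from a previous call) replays the training encoding.
encode_predictors <- function(x, meta = NULL) {
  x <- as.data.frame(x)
  if (!is.null(meta)) {
    miss <- setdiff(names(meta$columns), names(x))
    if (length(miss)) stop("missing predictor column(s): ",
                           paste(miss, collapse = ", "))
    extra <- setdiff(names(x), names(meta$columns))
    if (length(extra)) stop("unseen predictor column(s): ",
                            paste(extra, collapse = ", "))
    x <- x[names(meta$columns)]
  }
  cols <- list()
  spec <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
      spec[[nm]] <- list(type = "numeric")
    } else {
      v <- as.character(v)
      lev <- if (!is.null(meta)) meta$columns[[nm]]$levels else
        sort(unique(v[!is.na(v)]))
      if (!is.null(meta) && meta$columns[[nm]]$type == "numeric") {
        stop("column '", nm, "' was numeric in training")
      }
      if (length(lev) < 2L) lev <- union(lev, paste0(".", lev))
      if (length(lev) == 2L) {
        cols[[nm]] <- ifelse(is.na(v), NA_real_,
                             as.numeric(v == lev[2L]))
      } else {
        for (l in lev) {
          cols[[paste0(nm, "=", l)]] <-
            ifelse(is.na(v), NA_real_, as.numeric(v == l))
        }
      }
      spec[[nm]] <- list(type = "categorical", levels = lev)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  list(matrix = m, meta = list(columns = spec, encoded = colnames(m)))
}

#' Fit a Bayesian additive regression trees model
#'
#' Sum-of-trees regression by backfitting MCMC.  The response is rescaled
#' to [-0.5, 0.5]; each of the m trees carries a N(0, sigma_mu^2) leaf
#' prior with sigma_mu = 0.5/(k*sqrt(m)) and the
#' alpha*(1+depth)^(-beta) structure prior; the noise variance carries a
#' scaled-inverse-chi-squared(nu, lambda) prior with lambda solved from the
#' condition that a least-squares (or response-SD fallback) sigma estimate
#' sits at prior quantile q.  Trees move by Metropolis-Hastings
#' grow/prune/change proposals (0.28/0.28/0.44) with uniform split-rule
#' proposals over observed cutpoints; leaf values and sigma are Gibbs-drawn.
#' Missing predictor values are allowed when `use_missing_data` and are
#' routed by per-split direction flags sampled with each split.
#'
#' @param x predictor data.frame or matrix (categoricals auto-encoded;
#'   `NA` allowed only with `use_missing_data`).
#' @param y complete numeric response.
#' @param config a [bart_config()]; individual fields may also be passed
#'   via `...` for convenience.
#' @param ... overrides forwarded to [bart_config()] when `config` is NULL.
#' @return object of class `bart`: posterior draws (forest snapshots),
#'   `sigma` draws in response units, response scaling, column metadata,
#'   and the fitting config.  A fixed `seed` makes refits bit-identical.
#' @export
bart <- function(x, y, config = NULL, ...) {
  if (is.null(config)) config <- bart_config(...)
  y <- as.numeric(y)
  if (anyNA(y)) stop("response must be complete")
  if (length(y) < 20L) stop("need at least 20 rows")
  enc <- encode_predictors(x)
  X <- enc$matrix
  if (nrow(X) != length(y)) stop("x and y sizes differ")
  na_frac <- colMeans(is.na(X))
  if (any(na_frac == 1)) {
    stop("all-missing predictor column(s): ",
         paste(colnames(X)[na_frac == 1], collapse = ", "))
  }
  if (anyNA(X) && !config$use_missing_data) {
    stop("missing predictor values require use_missing_data = TRUE")
  }

  ymin <- min(y); ymax <- max(y)
  yrange <- ymax - ymin
  degenerate <- yrange == 0
  if (degenerate) yrange <- 1
  ys <- (y - (ymin + ymax) / 2) / yrange

  sighat <- sigma_estimate(X, ys)
  lambda <- sighat^2 * stats::qchisq(1 - config$q, config$nu) / config$nu
  sigma_mu <- 0.5 / (config$k * sqrt(config$num_trees))

  cutlist <- lapply(seq_len(ncol(X)), function(j) {
    v <- sort(unique(X[, j][!is.na(X[, j])]))
    if (length(v) < 2L) return(numeric(0))
    v <- v[-1L]  # cut rule is x < cut: cutting at the minimum is vacuous
    if (length(v) > 100L) {
      v <- unique(stats::quantile(v, seq(0, 1, length.out = 100L),
                                  names = FALSE, type = 1L))
    }
    v
  })

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- fit_bart_cpp(X, ys, cutlist, config$num_trees, sigma_mu,
                      config$nu, lambda, config$alpha, config$beta,
                      config$n_burn, config$n_draw,
                      config$use_missing_data, FALSE, sighat)
  structure(list(draws = res$draws,
                 sigma = res$sigma * yrange,
                 y_center = (ymin + ymax) / 2, y_scale = yrange,
                 meta = enc$meta, config = config,
                 n_train = nrow(X), sighat = sighat * yrange),
            class = "bart")
}

# Least-squares sigma estimate on scaled response; SD fallback when the
# linear fit is unusable (too few complete rows, collinearity).
sigma_estimate <- function(X, ys) {
  cc <- stats::complete.cases(X)
  est <- NA_real_
  if (sum(cc) > ncol(X) + 2L) {
    fit <- try(stats::lm.fit(cbind(1, X[cc, , drop = FALSE]), ys[cc]),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      dfree <- sum(cc) - fit$rank
      if (dfree > 0) est <- sqrt(sum(fit$residuals^2) / dfree)
    }
  }
  if (!is.finite(est) || est <= 0) est <- stats::sd(ys)
  if (!is.finite(est) || est <= 0) est <- 1e-6
  est
}

#' @export
print.bart <- function(x, ...) {
  cat("bart: sum of", x$config$num_trees, "trees,",
      length(x$sigma), "posterior draws,", x$n_train, "training rows\n")
  cat("sigma posterior mean:", format(mean(x$sigma), digits = 4), "\n")
  invisible(x)
}

#' Predict from a fitted BART model
#'
#' @param object a [bart()] fit.
#' @param newdata predictor table with the training columns; rows with
#'   missing values require a model trained with `use_missing_data`.
#' @param type `"mean"` for the posterior mean per row, `"draws"` for the
#'   full draws-by-rows matrix.
#' @param ... unused.
#' @return numeric vector (`"mean"`) or matrix (`"draws"`), response units.
#' @export
predict.bart <- function(object, newdata, type = c("mean", "draws"), ...) {
  type <- match.arg(type)
  enc <- encode_predictors(newdata, meta = object$meta)
  X <- enc$matrix[, object$meta$encoded, drop = FALSE]
  if (anyNA(X) && !object$config$use_missing_data) {
    stop("newdata has missing values but the model was trained with ",
         "use_missing_data = FALSE")
  }
  per_draw <- type == "draws"
  raw <- predict_bart_cpp(object$draws, X, per_draw)
  out <- raw * object$y_scale + object$y_center
  if (per_draw) out else as.numeric(out[1L, ])
}

#' Fit metrics for a BART model
#'
#' RMSE of the posterior-mean predictions and the pseudo-R^2
#' `1 - SSE/SST`, in-sample by default (pass held-out data for an
#' out-of-sample version).
#'
#' @param model a [bart()] fit.
#' @param x,y predictor table and response to evaluate on.
#' @return list of class `fit_metrics` with `r2` and `rmse`.
#' @export
fit_metrics <- function(model, x, y) {
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("zero-variance response: R^2 undefined")
  pred <- predict(model, x)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(r2 = 1 - sse / sst, rmse = sqrt(mean((y - pred)^2))),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat("r2 =", format(x$r2, digits = 3),
      " rmse =", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' Cross-validated hyperparameter selection
#'
#' k-fold cross-validation of out-of-sample RMSE over a grid of
#' configurations; returns the configuration with the lowest CV RMSE, ties
#' broken by smaller `num_trees` then smaller `k`.
#'
#' @param x,y training data.
#' @param grid list of [bart_config()] objects.
#' @param folds number of folds (>= 2).
#' @param seed seed for the fold assignment and fits.
#' @return list of class `bart_cv`: `best` (config), `rmse` (per-config CV
#'   RMSE), `fold_rmse` (config x fold matrix).
#' @export
bart_cv <- function(x, y, grid, folds = 5L, seed = NULL) {
  if (!length(grid)) stop("empty configuration grid")
  if (folds < 2L) stop("need at least 2 folds")
  x <- as.data.frame(x)
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (min(table(fold_id)) < 10L) stop("a fold has fewer than 10 rows")
  fold_rmse <- matrix(NA_real_, length(grid), folds)
  for (g in seq_along(grid)) {
    cfg <- grid[[g]]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- bart(x[tr, , drop = FALSE], y[tr], config = cfg)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      fold_rmse[g, f] <- sqrt(mean((y[!tr] - pred)^2))
    }
  }
  rmse <- rowMeans(fold_rmse)
  ord <- order(rmse,
               vapply(grid, `[[`, integer(1L), "num_trees"),
               vapply(grid, `[[`, numeric(1L), "k"))
  structure(list(best = grid[[ord[1L]]], rmse = rmse,
                 fold_rmse = fold_rmse, best_index = ord[1L]),
            class = "bart_cv")
}

#' The default CV grid
#'
#' The conventional search grid: k in {2, 3, 5}, (nu, q) in {(3, 0.9),
#' (3, 0.99), (10, 0.75)}, num_trees in {50, 200}.
#'
#' @param ... fields fixed across the grid (e.g. `n_burn`, `seed`,
#'   `use_missing_data`).
#' @return list of [bart_config()] objects.
#' @export
default_bart_grid <- function(...) {
  out <- list()
  for (m in c(50L, 200L)) for (k in c(2, 3, 5)) {
    for (nq in list(c(3, 0.9), c(3, 0.99), c(10, 0.75))) {
      out[[length(out) + 1L]] <-
        bart_config(num_trees = m, k = k, nu = nq[1L], q = nq[2L], ...)
    }
  }
  out
}

#' Archive a BART posterior to JSON
#'
#' Serializes the forest snapshots, noise draws, response scaling and
#' column metadata so a fitted model can be reloaded (e.g. to compute ALE
#' curves later) without refitting.
#'
#' @param model a [bart()] fit.
#' @param path output file.
#' @export
bart_archive <- function(model, path) {
  obj <- list(
    draws = lapply(model$draws, function(m) as.data.frame(m)),
    sigma = model$sigma, y_center = model$y_center, y_scale = model$y_scale,
    meta = model$meta, n_train = model$n_train, sighat = model$sighat,
    config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a BART posterior from a JSON archive
#'
#' @param path file written by [bart_archive()].
#' @return a `bart` object usable with [predict.bart()].
#' @export
bart_restore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  draws <- lapply(obj$draws, function(d) as.matrix(as.data.frame(d)))
  cfg <- obj$config
  config <- bart_config(num_trees = cfg$num_trees, k = cfg$k, nu = cfg$nu,
                        q = cfg$q, alpha = cfg$alpha, beta = cfg$beta,
                        n_burn = cfg$n_burn, n_draw = cfg$n_draw,
                        seed = cfg$seed,
                        use_missing_data = cfg$use_missing_data)
  meta <- obj$meta
  meta$columns <- lapply(meta$columns, function(cl) {
    cl$levels <- unlist(cl$levels)
    cl
  })
  structure(list(draws = draws, sigma = obj$sigma,
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 meta = meta, config = config,
                 n_train = obj$n_train, sighat = obj$sighat),
            class = "bart")
}

# Prior-only run of the tree sampler (no likelihood): used to check that
# the MCMC targets the alpha*(1+d)^(-beta) structure prior.
sample_tree_prior_mcmc <- function(n_iter, num_trees = 1L, alpha = 0.95,
                                   beta = 2, n = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::runif(n * 2L), n, 2L)
  cutlist <- lapply(1:2, function(j) sort(unique(X[, j]))[-1L])
  res <- fit_bart_cpp(X, rep(0, n), cutlist, num_trees, 0.1, 3, 1,
                      alpha, beta, 0L, as.integer(n_iter), FALSE, TRUE, 1)
  forest_leaf_counts_cpp(res$draws)
}
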