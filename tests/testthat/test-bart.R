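test_that("degenerate and deterministic behaviour of the sampler", {
  set.seed(1)
  x <- data.frame(a = runif(50))
  y <- rep(3.7, 50)
  fit <- bart(x, y, config = quick_bart(seed = 1L))
  expect_true(all(abs(predict(fit, x) - 3.7) < 1e-6))
  expect_lt(mean(fit$sigma), 1e-3)

  # fixed seed => bit-identical posterior
  y2 <- 2 * x$a + rnorm(50, 0, 0.2)
  f1 <- bart(x, y2, config = quick_bart(seed = 99L))
  f2 <- bart(x, y2, config = quick_bart(seed = 99L))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$sigma, f2$sigma)

  # row-wise purity: permuting rows permutes predictions
  xt <- data.frame(a = runif(30))
  p <- predict(f1, xt)
  perm <- sample(30)
  expect_equal(predict(f1, xt[perm, , drop = FALSE]), p[perm])

  expect_error(bart(x, c(y2[-1], NA)), "complete")
  expect_error(bart(x[1:10, , drop = FALSE], y[1:10]), "20 rows")
  expect_error(bart(data.frame(a = rep(NA_real_, 50)), y,
                    config = quick_bart(use_missing_data = TRUE)),
               "all-missing")
  expect_error(predict(f1, data.frame(b = 1:5)), "missing predictor")
})

test_that("the sampler recovers a linear signal and its noise level", {
  set.seed(2)
  n <- 200L
  x <- data.frame(x = runif(n, 0, 5))
  y <- 2 * x$x + rnorm(n, 0, 0.1)
  fit <- bart(x, y, num_trees = 50L, n_burn = 500L, n_draw = 500L, seed = 42L)
  xt <- data.frame(x = runif(200, 0, 5))
  yt <- 2 * xt$x
  pt <- predict(fit, xt)
  expect_gt(1 - sum((yt - pt)^2) / sum((yt - mean(yt))^2), 0.9)
  # slope between x = 0 and x = 1 within 20% of 2
  d <- diff(predict(fit, data.frame(x = c(0, 1))))
  expect_lt(abs(d - 2) / 2, 0.2)

  # sigma posterior concentrates near the truth on a larger sample
  set.seed(3)
  n <- 1000L
  x2 <- data.frame(x = runif(n))
  y2 <- 3 * x2$x + rnorm(n, 0, 0.5)
  fit2 <- bart(x2, y2, num_trees = 50L, n_burn = 400L, n_draw = 400L,
               seed = 7L)
  expect_lt(abs(mean(fit2$sigma) - 0.5) / 0.5, 0.25)
})

test_that("missing-data routing exploits informative missingness", {
  set.seed(4)
  n <- 600L
  x1 <- runif(n); x2 <- runif(n)
  hole <- runif(n) < 0.4
  y <- 2 * x2 + 3 * hole + rnorm(n, 0, 0.3)
  x1[hole] <- NA
  train <- seq_len(400L); test <- 401:600
  xm <- data.frame(x1 = x1, x2 = x2)
  fit_mia <- bart(xm[train, ], y[train],
                  config = quick_bart(use_missing_data = TRUE, seed = 5L))
  fit_no <- bart(data.frame(x2 = x2[train]), y[train],
                 config = quick_bart(seed = 5L))
  r2 <- function(p) 1 - sum((y[test] - p)^2) / sum((y[test] - mean(y[test]))^2)
  expect_gt(r2(predict(fit_mia, xm[test, ])), r2(predict(fit_no,
            data.frame(x2 = x2[test]))))
  expect_error(predict(fit_no, data.frame(x2 = c(NA, x2[test[-1]]))),
               "use_missing_data")
})

test_that("tree depths under the prior alone match the regularization prior", {
  # MCMC with the likelihood switched off, against direct simulation of
  # P(nonterminal at depth d) = 0.95 (1+d)^-2
  leaves_mcmc <- gaitcausal:::sample_tree_prior_mcmc(6000L, seed = 31L)
  sim_tree <- function(d) {
    if (runif(1) < 0.95 * (1 + d)^-2) {
      sim_tree(d + 1) + sim_tree(d + 1)
    } else 1L
  }
  set.seed(32)
  leaves_direct <- replicate(6000L, sim_tree(0))
  expect_lt(abs(mean(leaves_mcmc) - mean(leaves_direct)), 0.25)
  # stump frequency ~ 1 - 0.95
  expect_lt(abs(mean(leaves_mcmc == 1L) - mean(leaves_direct == 1L)), 0.05)
})

test_that("fit metrics and cross-validation behave as defined", {
  set.seed(6)
  n <- 150L
  x <- data.frame(x = runif(n, 0, 5))
  y <- 2 * x$x + rnorm(n, 0, 0.05)
  fit <- bart(x, y, config = quick_bart(seed = 2L))
  m <- fit_metrics(fit, x, y)
  expect_gt(m$r2, 0.98)
  expect_lt(m$rmse, 0.3)
  expect_error(fit_metrics(fit, x, rep(1, n)), "zero-variance")

  # in-sample beats held-out (overfitting direction)
  xt <- data.frame(x = runif(100, 0, 5))
  yt <- 2 * xt$x + rnorm(100, 0, 0.05)
  expect_gt(m$r2, fit_metrics(fit, xt, yt)$r2)

  # single-config grid returns that config; argmin by construction
  one <- bart_cv(x, y, list(quick_bart(seed = 3L)), folds = 3L, seed = 9L)
  expect_identical(one$best_index, 1L)
  grid <- list(quick_bart(k = 2, seed = 3L), quick_bart(k = 5, seed = 3L))
  sel <- bart_cv(x, y, grid, folds = 3L, seed = 9L)
  expect_identical(sel$best_index, which.min(sel$rmse))
  expect_identical(sel$best, grid[[sel$best_index]])
  expect_error(bart_cv(x[1:20, , drop = FALSE], y[1:20], grid, folds = 3L),
               "fewer than 10")
})

test_that("a posterior archived to JSON restores to identical predictions", {
  set.seed(8)
  x <- data.frame(a = runif(60), s = sample(c("F", "M"), 60, TRUE))
  y <- 2 * x$a + (x$s == "M") + rnorm(60, 0, 0.2)
  fit <- bart(x, y, config = quick_bart(seed = 11L))
  f <- tempfile(fileext = ".json")
  bart_archive(fit, f)
  back <- bart_restore(f)
  xt <- data.frame(a = runif(20), s = sample(c("F", "M"), 20, TRUE))
  expect_equal(predict(back, xt), predict(fit, xt), tolerance = 1e-12)
})
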