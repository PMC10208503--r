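test_that("ALE is exact for additive predictors and flat for ignored ones", {
  set.seed(51)
  n <- 2000L
  x1 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x1 + 0.5 * rnorm(n))  # strongly correlated

  flat <- compute_ale(function(nd) 5 + 2 * nd$x2, d, "x1", bins = 20L)
  expect_true(all(abs(flat$effect) < 1e-10))

  # additive 3*x1 component: every interior segment slope equals 3
  lin <- compute_ale(function(nd) 3 * nd$x1 + sin(nd$x2), d, "x1", bins = 20L)
  slopes <- diff(lin$effect) / diff(lin$edges)
  expect_true(all(abs(slopes - 3) < 0.15))

  # centering: count-weighted mean of the interpolated curve ~ 0
  interp <- approx(lin$edges, lin$effect, xout = d$x1, rule = 2)$y
  expect_lt(abs(mean(interp)), 1e-8)

  # pure interaction with a symmetric independent partner averages out
  d2 <- data.frame(x1 = rnorm(4000L), x2 = rnorm(4000L))
  inter <- compute_ale(function(nd) nd$x1 * nd$x2, d2, "x1", bins = 20L)
  expect_lt(max(abs(inter$effect)), 0.3)

  expect_error(compute_ale(function(nd) nd$x1, d, "x1", bins = 1L), "2 bins")
  expect_error(compute_ale(function(nd) 0, d, "nope"), "unknown factor")
})

test_that("rows missing the factor are dropped and duplicate edges merge", {
  d <- data.frame(x1 = c(rep(1, 50), rep(2, 30), rep(5, 20), NA, NA),
                  x2 = rnorm(102))
  cv <- compute_ale(function(nd) nd$x1, d, "x1", bins = 40L)
  expect_lte(length(cv$edges), 4L)  # only 3 distinct values survive
  expect_equal(sum(cv$counts), 100L)
})

test_that("posterior uncertainty bands are honest in the obvious limits", {
  set.seed(52)
  n <- 200L
  x <- data.frame(x = runif(n, 0, 5))
  y <- rep(2, n)
  degen <- bart(x, y, config = quick_bart(seed = 3L))
  band <- ale_uncertainty(degen, x, "x", bins = 10L)
  expect_lt(max(band$upper - band$lower), 1e-5)

  # band width shrinks with sample size on the same generative model
  fit_at <- function(n, seed) {
    set.seed(seed)
    x <- data.frame(x = runif(n, 0, 5))
    y <- 2 * x$x + rnorm(n, 0, 0.5)
    list(fit = bart(x, y, config = quick_bart(seed = seed)), x = x, y = y)
  }
  small <- fit_at(200L, 61L)
  big <- fit_at(2000L, 62L)
  b_small <- ale_uncertainty(small$fit, small$x, "x", bins = 10L)
  b_big <- ale_uncertainty(big$fit, big$x, "x", bins = 10L)
  expect_lt(mean(b_big$upper - b_big$lower),
            mean(b_small$upper - b_small$lower))

  # calibration: the true centered component sits inside the band at
  # >= 80% of edges on a well-specified nonlinear simulation
  set.seed(62)
  xs <- data.frame(x = runif(800, 0, 5))
  ys <- sin(xs$x) + rnorm(800)
  fit <- bart(xs, ys, config = bart_config(num_trees = 50L, n_burn = 300L,
                                           n_draw = 300L, seed = 62L))
  b <- ale_uncertainty(fit, xs, "x", bins = 10L)
  truth <- sin(b$edges)
  truth <- truth - mean(approx(b$edges, truth, xout = xs$x)$y)
  covered <- truth >= b$lower - 1e-9 & truth <= b$upper + 1e-9
  expect_gte(mean(covered), 0.8)

  short <- bart(small$x, small$y,
                config = bart_config(num_trees = 20L, n_burn = 50L,
                                     n_draw = 10L, seed = 1L))
  expect_error(ale_uncertainty(short, small$x, "x"), "longer chain")
})

test_that("effect size is the curve range over the middle 95% window", {
  set.seed(53)
  vals <- rnorm(1e5)
  edges <- seq(-5, 5, length.out = 41L)
  lin <- structure(list(factor = "x", edges = edges, effect = edges,
                        counts = rep(1L, 40L), x_sample = vals),
                   class = "ale_curve")
  es <- effect_size(lin)
  # linear slope-1 curve: range = P97.5 - P2.5 of a standard normal sample
  expect_equal(es$effect, 2 * qnorm(0.975), tolerance = 0.05)
  expect_equal(es$effect, diff(es$window), tolerance = 1e-9)  # monotone curve

  flat <- lin; flat$effect <- rep(1.3, 41L)
  expect_equal(effect_size(flat)$effect, 0)

  # invariant to adding a constant
  shifted <- lin; shifted$effect <- lin$effect + 100
  expect_equal(effect_size(shifted)$effect, es$effect)

  expect_error(effect_size(lin, factor_values = rep(1, 100)), "collapses")

  # interval from per-draw curves; identical draws give zero width
  lin$draws <- matrix(rep(edges, each = 30L), 30L)
  es2 <- effect_size(lin)
  expect_equal(es2$lower, es2$upper)
  expect_equal(es2$lower, es2$effect, tolerance = 1e-9)
})

test_that("curves export as a tidy table", {
  set.seed(54)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  cv <- compute_ale(function(nd) nd$x1, d, "x1", bins = 10L)
  tab <- ale_table(list(cv))
  expect_named(tab, c("factor", "edge", "effect", "lo", "hi", "n"))
  expect_equal(nrow(tab), length(cv$edges))
  f <- tempfile(fileext = ".csv")
  ale_table(list(cv), f)
  expect_true(file.exists(f))
})
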