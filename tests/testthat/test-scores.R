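test_that("polychoric correlation behaves at the reference points", {
  # independence pattern: counts proportional to the product of margins
  tab <- outer(c(3000, 4000, 3000), c(5000, 5000)) / 10000
  expect_lt(abs(polychoric_correlation(tab)), 0.03)

  # perfect concordance clips at the boundary
  expect_equal(polychoric_correlation(matrix(c(50, 0, 0, 50), 2L)), 0.999)
  expect_equal(polychoric_correlation(matrix(c(0, 50, 50, 0), 2L)), -0.999)

  # degenerate margin names the offending item (rows = first item)
  bad <- matrix(c(10, 0, 12, 0), 2L)
  expect_error(polychoric_correlation(bad, items = c("hipL", "hipR")),
               "hipL")
  expect_error(polychoric_correlation(t(bad), items = c("hipL", "hipR")),
               "hipR")
})

test_that("polychoric correlation recovers the latent correlation and is antisymmetric", {
  set.seed(42)
  for (rho in c(-0.7, 0, 0.6)) {
    tab <- bvn_ordinal_table(5000L, rho)
    expect_lt(abs(polychoric_correlation(tab) - rho), 0.05)
  }
  # reversing one item's category order flips the sign
  tab <- bvn_ordinal_table(3000L, 0.5)
  rev_tab <- tab[, rev(seq_len(ncol(tab)))]
  expect_equal(polychoric_correlation(rev_tab),
               -polychoric_correlation(tab), tolerance = 1e-3)
})

test_that("the polychoric matrix is PSD with unit diagonal and finds a shared factor", {
  set.seed(7)
  n <- 2000L
  # independent uniform ratings: off-diagonals near zero
  ind <- matrix(sample(1:5, n * 4L, replace = TRUE), n, 4L)
  r <- polychoric_matrix(ind)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # all items copies of one shared rating: clipped perfect correlations
  shared <- sample(1:5, n, replace = TRUE)
  same <- cbind(shared, shared, shared)
  r2 <- polychoric_matrix(same)
  expect_true(all(abs(r2[upper.tri(r2)] - 0.999) < 1e-6))

  # one latent severity with loading 0.8: dominant first component
  lat <- rnorm(3000L)
  items <- vapply(1:6, function(j) {
    z <- 0.8 * lat + sqrt(1 - 0.64) * rnorm(3000L)
    findInterval(z, c(-1, 0, 1)) + 1
  }, numeric(3000L))
  r3 <- polychoric_matrix(items)
  ev <- eigen(r3, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1L] / sum(ev), 0.5)

  expect_error(polychoric_matrix(cbind(a = rep(1, 50), b = sample(1:2, 50, TRUE))),
               "constant")
})

test_that("summary scores are monotone, complete-case only, and track latent severity", {
  set.seed(11)
  n <- 2000L
  lat <- rnorm(n)
  m <- vapply(1:12, function(j) {
    z <- lat + 0.7 * rnorm(n)
    findInterval(z, c(-0.9, 0.35, 1.4, 2.4)) + 1
  }, numeric(n))
  colnames(m) <- as.vector(outer(exam_muscles, exam_sides, paste, sep = "."))
  rownames(m) <- sprintf("c%04d", seq_len(n))

  sm <- summary_score(m, "spasticity")
  expect_equal(mean(sm$score, na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(sd(sm$score, na.rm = TRUE), 1, tolerance = 1e-8)
  expect_gt(cor(sm$score, lat), 0.8)

  # a child rating uniformly higher than another scores strictly higher
  hi <- which.max(rowMeans(m)); lo <- which.min(rowMeans(m))
  expect_gt(sm$score[hi], sm$score[lo])

  # any missing item means a missing score
  m2 <- m
  m2[1L, 3L] <- NA
  sm2 <- summary_score(m2, "spasticity")
  expect_true(is.na(sm2$score[1L]))
  expect_false(anyNA(sm2$score[-1L]))

  # invariant to item (column) ordering
  perm <- sample(ncol(m))
  sm3 <- summary_score(m[, perm], "spasticity")
  expect_equal(unname(sm3$score), unname(sm$score), tolerance = 1e-8)
})

test_that("long exam tables reshape and score end to end", {
  set.seed(3)
  sim <- generate_cohort(synthetic_config(n = 400L, seed = 8L))
  sm <- summary_score(sim$exams, "smc")
  truth <- sim$cohort$smc[match(names(sm$score), sim$cohort$id)]
  ok <- !is.na(sm$score) & !is.na(truth)
  expect_gt(cor(sm$score[ok], truth[ok]), 0.8)
  expect_error(exam_item_matrix(sim$exams, "gait"), "'arg' should be one of")
})

test_that("net metabolic power applies the 20.1 J/mL conversion linearly", {
  expect_equal(net_metabolic_power(10, 3.8), 124.62)
  expect_equal(net_metabolic_power(6.2, 0), 124.62)
  expect_equal(net_metabolic_power(4.4, 4.4), 0)
  # linear in both arguments with slope +/- 20.1
  expect_equal(net_metabolic_power(5 + 1, 2) - net_metabolic_power(5, 2), 20.1)
  expect_equal(net_metabolic_power(5, 2 + 1) - net_metabolic_power(5, 2), -20.1)
  expect_warning(p <- net_metabolic_power(3, 4), "resting")
  expect_equal(p, -20.1)
  expect_error(net_metabolic_power(-1, 0), "nonnegative")
})

test_that("z-normalization centers, flips spasticity, and round-trips", {
  set.seed(5)
  co <- data.frame(gdi = rnorm(200, 70, 10),
                   spasticity = rnorm(200, 0, 1.2),
                   strength = c(rnorm(198), NA, NA))
  z <- zscore_factors(co)
  expect_equal(mean(z$data$gdi), 0, tolerance = 1e-12)
  expect_equal(sd(z$data$gdi), 1, tolerance = 1e-12)
  # most spastic child gets the most negative normalized value
  expect_equal(which.min(z$data$spasticity), which.max(co$spasticity))
  # missing-aware scaling and exact inverse transform
  back <- unzscore_factors(z)
  expect_equal(back$gdi, co$gdi, tolerance = 1e-9)
  expect_equal(back$spasticity, co$spasticity, tolerance = 1e-9)
  expect_equal(back$strength, co$strength, tolerance = 1e-9)
  expect_error(zscore_factors(data.frame(gdi = rep(1, 10))), "zero variance")
})

test_that("cohort and exam readers apply column maps", {
  co <- data.frame(PatientAge = c(8, 10), GDI_score = c(65, 80),
                   power = c(110, 140))
  f <- tempfile(fileext = ".csv")
  write.csv(co, f, row.names = FALSE)
  got <- read_cohort(f, column_map = c(age = "PatientAge", gdi = "GDI_score"))
  expect_equal(got$age, c(8, 10))
  expect_equal(got$gdi, c(65, 80))
  expect_error(read_cohort(f, column_map = c(age = "NoSuch")), "NoSuch")

  ex <- data.frame(child = "c1", domain = "smc", muscle = "hip_flexors",
                   side = "L", rating = 2)
  fe <- tempfile(fileext = ".csv")
  write.csv(ex, fe, row.names = FALSE)
  expect_silent(read_exams(fe))
  write.csv(ex[, -5], fe, row.names = FALSE)
  expect_error(read_exams(fe), "rating")
})
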