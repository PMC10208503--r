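test_that("the generator is seed-deterministic and hits the published marginals", {
  a <- generate_cohort(synthetic_config(n = 500L, seed = 17L))
  b <- generate_cohort(synthetic_config(n = 500L, seed = 17L))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$exams, b$exams)
  c2 <- generate_cohort(synthetic_config(n = 500L, seed = 18L))
  expect_false(identical(a$cohort$power, c2$cohort$power))

  big <- generate_cohort(synthetic_config(n = 5000L, seed = 11L))
  co <- big$cohort
  expect_lt(abs(median(co$gdi, na.rm = TRUE) - 71.1), 3)
  expect_lt(abs(median(co$power) - 124.2), 10)
  expect_lt(abs(median(co$speed) - 0.79), 0.06)
  expect_lt(abs(mean(is.na(co$dmc)) - 0.321), 0.02)
  expect_lt(abs(mean(is.na(co$spasticity)) - 0.183), 0.02)
  expect_lt(abs(mean(is.na(co$strength)) - 0.177), 0.02)
  expect_lt(abs(mean(is.na(co$smc)) - 0.175), 0.02)
  expect_lt(abs(mean(is.na(co$gdi)) - 0.006), 0.005)
  expect_lt(abs(mean(co$gmfcs == "II") - 0.464), 0.03)

  s <- dataset_summary(co)
  expect_equal(s$columns$missing[s$columns$column == "dmc"],
               mean(is.na(co$dmc)))
  one <- dataset_summary(co[3L, ])
  expect_equal(one$columns$median[one$columns$column == "power"],
               co$power[3L])

  # ordinal items stay on their scales
  r <- big$exams$rating
  expect_true(all(r[big$exams$domain == "smc"] %in% 0:2))
  expect_true(all(r[big$exams$domain == "spasticity"] %in% 1:5))
  expect_true(all(r[big$exams$domain == "strength"] %in% 1:5))
})

test_that("switched-off structural effects give a constant outcome and zero effects", {
  cf <- modifyList(synthetic_coefficients(),
                   list(p0 = 100, p_mass = 0, p_speed = 0, p_gdi = 0,
                        p_dmc = 0, p_smc = 0, p_sp = 0, p_str = 0,
                        p_age = 0, p_height = 0, p_noise = 0))
  sim <- generate_cohort(synthetic_config(n = 300L, seed = 2L, coef = cf))
  expect_true(all(sim$cohort$power == 100))
  for (f in c("gdi", "spasticity", "strength")) {
    expect_equal(true_total_effect(sim$truth, f, -1, 1, mc_n = 500L), 0)
  }
  expect_error(true_total_effect(sim$truth, "sex", 0, 1), "unknown factor")
})

test_that("linear-link total effects match the analytic path rule", {
  sim <- generate_cohort(synthetic_config(n = 100L, seed = 5L,
                                          links = "linear"))
  ln <- synthetic_coefficients()$lin
  via_gdi <- ln$p_gdi
  via_speed <- ln$p_speed + ln$g_speed * ln$p_gdi
  expected <- c(
    gdi = ln$p_gdi,
    smc = ln$p_smc + ln$s_smc * via_speed + ln$g_smc * via_gdi,
    spasticity = ln$p_sp + ln$s_sp * via_speed + ln$g_sp * via_gdi,
    strength = ln$p_st + ln$s_st * via_speed + ln$g_st * via_gdi)
  for (f in names(expected)) {
    from <- if (f == "gdi") 70 else 0
    got <- true_total_effect(sim$truth, f, from, from + 1,
                             mc_n = 40000L, seed = 9L)
    expect_equal(got, unname(expected[f]), tolerance = 0.05)
  }
})

test_that("under the default links GDI dominates and strength is smallest", {
  sim <- generate_cohort(synthetic_config(n = 3000L, seed = 11L))
  co <- sim$cohort
  eff <- vapply(c("gdi", "dmc", "smc", "spasticity", "strength"),
                function(f) true_effect_size(sim$truth, f, co[[f]],
                                             grid_n = 9L, mc_n = 4000L,
                                             seed = 3L)$effect,
                numeric(1L))
  expect_identical(names(which.max(eff)), "gdi")
  expect_identical(names(which.min(eff)), "strength")
  # the inverted-U strength link: interior of the dose-response curve rises
  # above both window endpoints
  st <- true_effect_size(sim$truth, "strength", co$strength, grid_n = 15L,
                         mc_n = 6000L, seed = 4L)
  expect_gt(max(st$curve), max(st$curve[1L], st$curve[15L]) + 1)
})

test_that("MAR missingness concentrates DMC holes in more affected children", {
  sim <- generate_cohort(synthetic_config(n = 6000L, seed = 23L,
                                          mechanism = "MAR"))
  co <- sim$cohort
  expect_lt(abs(mean(is.na(co$dmc)) - 0.321), 0.03)
  rI <- mean(is.na(co$dmc[co$gmfcs == "I"]))
  rIII <- mean(is.na(co$dmc[co$gmfcs == "III"]))
  expect_gt(rIII, rI)
})

test_that("cohorts round-trip through the plain-text writers", {
  sim <- generate_cohort(synthetic_config(n = 120L, seed = 6L))
  dir <- tempfile()
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths["cohort"])
  expect_equal(back$power, sim$cohort$power, tolerance = 1e-9)
  expect_equal(nrow(read_exams(paths["exams"])), nrow(sim$exams))
})
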