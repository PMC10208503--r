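# Synthetic cohort generator: a structural equation model over the pinned
# causal graph, calibrated once to the published cohort's marginals (median
# GDI 71.1, median net power 124.2 W, median speed 0.79 m/s, the GMFCS
# split, the missingness rates) and then frozen.  The generator is the test
# bed for the whole pipeline: it knows its own structural equations, so
# do-intervention ground truth is available for any factor.

#' Default structural coefficients of the synthetic cohort
#'
#' Frozen calibration of the structural equation model.  Severity latents
#' are driven by a shared latent brain-injury severity; walking speed, GDI
#' and net power follow saturating (tanh / logistic) links so that factor
#' effects plateau at the extremes, with an inverted-U direct strength term
#' in the power equation; power is additive in watts with a mass main
#' effect and a linear speed cost.
#'
#' @return named list of coefficients.
#' @export
synthetic_coefficients <- function() {
  list(
    # demographics
    age_mean = 9.2, age_sd = 4.6, age_min = 3, age_max = 18,
    p_male = 0.562,
    h0 = 78, h1 = 6.0, h2 = -0.07, h_sex = 2.5, h_noise = 5.5,
    m0 = 11.6, m1 = 0.5, m_noise = 0.18,
    # impairment severity latents: sev = wb*B + wa*zage + ws*zheight + e
    wb = c(spasticity = 0.72, strength = 0.78, smc = 0.80, dmc = 0.76),
    wa = c(spasticity = -0.10, strength = -0.12, smc = -0.08, dmc = -0.10),
    ws = c(spasticity = -0.05, strength = -0.08, smc = -0.05, dmc = -0.05),
    dmc0 = 83.0, dmc1 = 9.5,
    # walking speed (m/s)
    s0 = 0.76, s_amp = 0.38, s_gain = 0.7,
    s_sp = -0.20, s_st = 0.28, s_smc = 0.30, s_dmc = 0.30,
    s_age = 0.25, s_height = 0.15, s_mass = -0.10, s_noise = 0.13,
    # GDI (points)
    g0 = 70.5, g_amp = 14, g_gain = 0.6,
    g_sp = -0.22, g_st = 0.25, g_smc = 0.33, g_dmc = 0.33,
    g_speed = 0.9, g_age = 0.05, g_height = 0.03, g_mass = -0.03,
    g_noise = 5.5,
    # net metabolic power (W)
    p0 = -127, p_mass = 3.45, p_speed = 52,
    p_gdi = 105, p_gdi_ctr = 70, p_gdi_w = 9.5,
    p_dmc = 42, p_dmc_ctr = 82, p_dmc_w = 8,
    p_smc = 38, p_smc_w = 0.9,
    p_sp = 34, p_sp_w = 0.9,
    p_str = 16, p_str_w = 1.1,
    p_age = 0.8, p_height = 0.15,
    p_noise = 21, p_floor = 5,
    sex_power = 0,
    # ordinal exam items
    item_noise = c(spasticity = 0.7, strength = 0.7, smc = 0.7),
    thr_spasticity = c(-0.9, 0.35, 1.4, 2.4),   # Ashworth 1-5
    thr_strength = c(-2.4, -1.4, -0.35, 0.9),   # Kendall 1-5 on -sev
    thr_smc = c(-0.55, 0.55),                   # SMC 0-2 on -sev
    # linear-link mode coefficients (for analytic path-rule checks)
    lin = list(
      s_sp = -0.05, s_st = 0.04, s_smc = 0.05, s_dmc = 0.05,
      g_sp = -2.0, g_st = 2.2, g_smc = 3.0, g_dmc = 3.0, g_speed = 8,
      p_gdi = -2.2, p_speed = 52,
      p_sp = 9, p_st = -4, p_smc = -8, p_dmc = -8)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param n number of children.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param missingness named rates for the maskable columns (defaults are
#'   the published rates: DMC 32.1%, spasticity 18.3%, strength 17.7%,
#'   SMC 17.5%, GDI 0.6%).
#' @param mechanism `"MCAR"` (default) or `"MAR"`, where DMC missingness
#'   increases with GMFCS level while keeping the overall rate.
#' @param links `"default"` (saturating links, inverted-U strength) or
#'   `"linear"` (all links linear; total effects then obey the path rule).
#' @param coef coefficient list; start from [synthetic_coefficients()] and
#'   override fields via `modifyList()` for experiments.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 2000L, seed = 1L,
                             missingness = c(dmc = 0.321, spasticity = 0.183,
                                             strength = 0.177, smc = 0.175,
                                             gdi = 0.006),
                             mechanism = c("MCAR", "MAR"),
                             links = c("default", "linear"),
                             coef = synthetic_coefficients()) {
  mechanism <- match.arg(mechanism)
  links <- match.arg(links)
  stopifnot(n >= 1L, all(missingness >= 0), all(missingness < 1))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 missingness = missingness, mechanism = mechanism,
                 links = links, coef = coef),
            class = "synthetic_config")
}

# Exogenous draws: everything random in the SEM, so that interventions can
# replay identical noise.
draw_exogenous <- function(n, cf) {
  age <- stats::qnorm(stats::runif(
    n, stats::pnorm(cf$age_min, cf$age_mean, cf$age_sd),
    stats::pnorm(cf$age_max, cf$age_mean, cf$age_sd)), cf$age_mean, cf$age_sd)
  list(
    n = n, age = age,
    sex = stats::rbinom(n, 1L, cf$p_male),
    b = stats::rnorm(n),
    e_height = stats::rnorm(n, 0, cf$h_noise),
    e_mass = stats::rnorm(n, 0, cf$m_noise),
    e_sev = matrix(stats::rnorm(n * 4L), n, 4L,
                   dimnames = list(NULL, c("spasticity", "strength",
                                           "smc", "dmc"))),
    e_speed = stats::rnorm(n, 0, cf$s_noise),
    e_gdi = stats::rnorm(n, 0, cf$g_noise),
    e_power = stats::rnorm(n, 0, cf$p_noise))
}

# Deterministic propagation of the structural equations given exogenous
# draws; `intervene` fixes named columns (do-operator), with everything
# downstream recomputed and everything upstream untouched.
propagate_sem <- function(ex, cf, links = "default", intervene = list()) {
  n <- ex$n
  iv <- function(nm, val) if (nm %in% names(intervene))
    rep_len(intervene[[nm]], n) else val

  age <- iv("age", ex$age)
  sex <- iv("sex", ex$sex)
  height <- iv("height",
               cf$h0 + cf$h1 * age + cf$h2 * age^2 + cf$h_sex * sex +
                 ex$e_height)
  mass <- iv("mass",
             (cf$m0 + cf$m1 * age) * (height / 100)^2 * exp(ex$e_mass))
  zage <- (age - 9.6) / 4
  zheight <- (height - 130) / 20

  sev <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, c("spasticity", "strength",
                                        "smc", "dmc")))
  for (d in colnames(sev)) {
    we <- sqrt(max(1 - cf$wb[[d]]^2 - cf$wa[[d]]^2 - cf$ws[[d]]^2, 0.05))
    sev[, d] <- cf$wb[[d]] * ex$b + cf$wa[[d]] * zage +
      cf$ws[[d]] * zheight + we * ex$e_sev[, d]
  }
  spasticity <- iv("spasticity", sev[, "spasticity"])
  strength <- iv("strength", -sev[, "strength"])
  smc <- iv("smc", -sev[, "smc"])
  dmc <- iv("dmc", cf$dmc0 + cf$dmc1 * (-sev[, "dmc"]))
  zdmc <- (dmc - cf$dmc0) / cf$dmc1

  if (links == "linear") {
    ln <- cf$lin
    speed <- iv("speed",
                cf$s0 + ln$s_sp * spasticity + ln$s_st * strength +
                  ln$s_smc * smc + ln$s_dmc * zdmc +
                  0.02 * zage + ex$e_speed)
    gdi <- iv("gdi",
              cf$g0 + ln$g_sp * spasticity + ln$g_st * strength +
                ln$g_smc * smc + ln$g_dmc * zdmc +
                ln$g_speed * (speed - cf$s0) + ex$e_gdi)
    power <- cf$p0 + cf$p_mass * mass + ln$p_speed * speed +
      ln$p_gdi * (gdi - cf$g0) + ln$p_sp * spasticity +
      ln$p_st * strength + ln$p_smc * smc + ln$p_dmc * zdmc +
      cf$sex_power * sex + ex$e_power
    power <- iv("power", power)
  } else {
    motor <- cf$s_sp * spasticity + cf$s_st * strength +
      cf$s_smc * smc + cf$s_dmc * zdmc
    speed <- iv("speed",
                pmax(cf$s0 + cf$s_amp *
                       tanh(cf$s_gain * (motor + cf$s_age * zage +
                                           cf$s_height * zheight +
                                           cf$s_mass * (mass / 30 - 1))) +
                       ex$e_speed, 0.05))
    gimp <- cf$g_sp * spasticity + cf$g_st * strength +
      cf$g_smc * smc + cf$g_dmc * zdmc
    gdi <- iv("gdi",
              cf$g0 + cf$g_amp *
                tanh(cf$g_gain * (gimp + cf$g_speed * (speed - 0.79) +
                                    cf$g_age * zage +
                                    cf$g_height * zheight +
                                    cf$g_mass * (mass / 30 - 1))) +
                ex$e_gdi)
    power <- cf$p0 + cf$p_mass * mass + cf$p_speed * speed +
      cf$p_gdi * stats::plogis(-(gdi - cf$p_gdi_ctr) / cf$p_gdi_w) +
      cf$p_dmc * stats::plogis(-(dmc - cf$p_dmc_ctr) / cf$p_dmc_w) +
      cf$p_smc * stats::plogis(-smc / cf$p_smc_w) +
      cf$p_sp * stats::plogis(spasticity / cf$p_sp_w) +
      cf$p_str * exp(-(strength / cf$p_str_w)^2 / 2) +
      cf$p_age * zage + cf$p_height * zheight +
      cf$sex_power * sex + ex$e_power
    power <- iv("power", pmax(power, cf$p_floor))
  }
  if (!all(is.finite(power))) stop("non-finite net power; check coefficients")

  # GMFCS by severity terciles matching the published level split
  comp <- rowMeans(sev)
  cuts <- stats::quantile(comp, c(0.307, 0.771), names = FALSE)
  gmfcs <- cut(comp, c(-Inf, cuts, Inf), labels = c("I", "II", "III"))

  data.frame(id = sprintf("child%05d", seq_len(n)),
             age = age, sex = ifelse(sex == 1, "M", "F"),
             height = height, mass = mass, speed = speed,
             gdi = gdi, dmc = dmc, smc = smc,
             spasticity = spasticity, strength = strength,
             power = power, gmfcs = as.character(gmfcs),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Samples exogenous demographics and a latent brain-injury severity,
#' propagates the structural equations of the pinned causal graph in
#' topological order, derives per-muscle ordinal exam items by thresholding
#' noisy copies of the domain severities, assigns GMFCS by severity
#' terciles, and finally applies the missingness masks.  The returned
#' ground-truth object closes over the exact structural equations, so
#' do-intervention effects can be computed for any factor.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`: `cohort` (one row per child,
#'   missingness applied), `exams` (long ordinal item table for children
#'   whose domain score is observed), `truth` (class `ground_truth`),
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cf <- config$coef
  set.seed(config$seed)
  ex <- draw_exogenous(config$n, cf)
  cohort <- propagate_sem(ex, cf, config$links)

  # ordinal exam items from noisy copies of the domain severities
  sev_obs <- cbind(spasticity = cohort$spasticity,
                   strength = -cohort$strength,
                   smc = -cohort$smc)
  items <- as.vector(outer(exam_muscles, exam_sides, paste, sep = "."))
  exam_rows <- vector("list", 3L)
  names(exam_rows) <- colnames(sev_obs)
  for (d in colnames(sev_obs)) {
    lat <- sev_obs[, d] +
      matrix(stats::rnorm(config$n * 12L, 0, cf$item_noise[[d]]),
             config$n, 12L)
    if (d != "spasticity") lat <- -lat  # higher rating = stronger / better
    thr <- cf[[paste0("thr_", d)]]
    first <- if (d == "smc") 0L else 1L
    rate <- findInterval(lat, thr) + first
    exam_rows[[d]] <- data.frame(
      child = rep(cohort$id, 12L),
      domain = d,
      muscle = rep(rep(exam_muscles, each = config$n), 2L),
      side = rep(exam_sides, each = config$n * 6L),
      rating = as.vector(rate),
      stringsAsFactors = FALSE)
  }

  # missingness masks (last step)
  miss <- config$missingness
  masked <- cohort
  for (col in names(miss)) {
    rate <- miss[[col]]
    if (rate <= 0) next
    if (config$mechanism == "MAR" && col == "dmc") {
      w <- c(I = 0.6, II = 1.0, III = 1.6)[masked$gmfcs]
      pr <- pmin(rate * w / mean(w[masked$gmfcs]), 0.95)
      # renormalize so the expected overall rate matches
      pr <- pmin(pr * rate / mean(pr), 0.95)
      hit <- stats::runif(config$n) < pr
    } else {
      hit <- stats::runif(config$n) < rate
    }
    masked[[col]][hit] <- NA
  }
  exams <- do.call(rbind, lapply(names(exam_rows), function(d) {
    keep_ids <- masked$id[!is.na(masked[[d]])]
    exam_rows[[d]][exam_rows[[d]]$child %in% keep_ids, , drop = FALSE]
  }))
  rownames(exams) <- NULL

  truth <- structure(list(coef = cf, links = config$links,
                          seed = config$seed, n = config$n),
                     class = "ground_truth")
  structure(list(cohort = masked, exams = exams, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Ground-truth total effect of an intervention
#'
#' Monte-Carlo contrast of mean net power under `do(factor = to)` versus
#' `do(factor = from)`: fresh exogenous draws are propagated twice with the
#' factor clamped, so all descendants of the factor (walking speed, GDI)
#' respond naturally while its non-descendants keep their sampled values —
#' the total (direct plus mediated) effect.
#'
#' @param truth `ground_truth` from [generate_cohort()].
#' @param factor one of `"gdi"`, `"dmc"`, `"smc"`, `"spasticity"`,
#'   `"strength"`, `"speed"`.
#' @param from,to intervention values.
#' @param mc_n Monte-Carlo sample size.
#' @param seed seed for the Monte-Carlo draws.
#' @return mean power difference in watts (`to` minus `from`).
#' @export
true_total_effect <- function(truth, factor, from, to, mc_n = 20000L,
                              seed = 1L) {
  curve <- true_effect_curve(truth, factor, c(from, to), mc_n, seed)
  curve[2L] - curve[1L]
}

#' Ground-truth dose-response curve of an intervention
#'
#' @param truth `ground_truth` object.
#' @param factor intervened factor (see [true_total_effect()]).
#' @param values vector of intervention values.
#' @param mc_n,seed Monte-Carlo controls.
#' @return numeric vector: mean power under `do(factor = v)` for each `v`.
#' @export
true_effect_curve <- function(truth, factor, values, mc_n = 20000L,
                              seed = 1L) {
  ok <- c("gdi", "dmc", "smc", "spasticity", "strength", "speed")
  if (!factor %in% ok) stop("unknown factor: ", factor)
  set.seed(seed)
  ex <- draw_exogenous(as.integer(mc_n), truth$coef)
  vapply(values, function(v) {
    co <- propagate_sem(ex, truth$coef, truth$links,
                        intervene = stats::setNames(list(v), factor))
    mean(co$power)
  }, numeric(1L))
}

#' Ground-truth effect size over the middle 95% of the sample
#'
#' Range of the do-intervention dose-response curve over the factor's
#' central [2.5th, 97.5th] percentile window — the ground-truth analogue of
#' the ALE [effect_size()].
#'
#' @param truth `ground_truth` object.
#' @param factor intervened factor.
#' @param factor_values observed sample of the factor (defines the window).
#' @param grid_n number of grid points across the window.
#' @param mc_n,seed Monte-Carlo controls.
#' @return list: `effect` (watts), `window`, `grid`, `curve`.
#' @export
true_effect_size <- function(truth, factor, factor_values, grid_n = 21L,
                             mc_n = 20000L, seed = 1L) {
  w <- stats::quantile(factor_values, c(0.025, 0.975), names = FALSE,
                       na.rm = TRUE)
  grid <- seq(w[1L], w[2L], length.out = grid_n)
  curve <- true_effect_curve(truth, factor, grid, mc_n, seed)
  list(effect = max(curve) - min(curve), window = w, grid = grid,
       curve = curve)
}

#' Summarize a cohort table
#'
#' Missing-aware medians and SDs per numeric column, missing fractions,
#' and GMFCS level counts, in the layout of a participant-characteristics
#' table.
#'
#' @param cohort data.frame (a generated or read cohort).
#' @return list of class `cohort_summary`: `columns` data.frame (median,
#'   sd, n, missing fraction), `gmfcs` counts, `n`.
#' @export
dataset_summary <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  num <- names(cohort)[vapply(cohort, is.numeric, logical(1L))]
  tab <- data.frame(
    column = num,
    median = vapply(num, function(c) stats::median(cohort[[c]], na.rm = TRUE),
                    numeric(1L)),
    sd = vapply(num, function(c) stats::sd(cohort[[c]], na.rm = TRUE),
                numeric(1L)),
    n = vapply(num, function(c) sum(!is.na(cohort[[c]])), integer(1L)),
    missing = vapply(num, function(c) mean(is.na(cohort[[c]])), numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  gm <- if ("gmfcs" %in% names(cohort)) table(cohort$gmfcs) else NULL
  structure(list(columns = tab, gmfcs = gm, n = nrow(cohort)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort of", x$n, "children\n")
  disp <- x$columns
  disp$median <- round(disp$median, 2)
  disp$sd <- round(disp$sd, 2)
  disp$missing <- paste0(round(100 * disp$missing, 1), "%")
  print(disp, row.names = FALSE)
  if (!is.null(x$gmfcs)) {
    cat("GMFCS: ", paste(names(x$gmfcs), as.integer(x$gmfcs),
                         sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' @param sim a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (cohort CSV, exams CSV, truth
#'   config JSON).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             exams = file.path(dir, "exams.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(sim$exams, paths["exams"], row.names = FALSE)
  jsonlite::write_json(
    list(links = sim$truth$links, seed = sim$truth$seed, n = sim$truth$n,
         coef = sim$truth$coef),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
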