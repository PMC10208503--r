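# End-to-end analysis: summary scores -> plausibility check -> adjustment
# sets -> one BART model per distinct predictor set -> ALE curves and
# effect sizes -> ranked report.

default_var_map <- c(Age = "age", Sex = "sex", Height = "height",
                     Mass = "mass", Speed = "speed", GDI = "gdi",
                     DMC = "dmc", SMC = "smc", Spasticity = "spasticity",
                     Strength = "strength", MetPower = "power")

#' Run the full causal analysis
#'
#' Orchestrates the pipeline on a cohort table: (1) tests the plausibility
#' of the causal model via its implied conditional independencies; (2)
#' computes the minimal backdoor adjustment set of every exposure on the
#' outcome; (3) groups exposures whose predictor set (exposure plus its
#' adjustment set) coincides and fits one BART model per group, with
#' missing-data routing on; (4) computes each exposure's ALE curve with a
#' posterior uncertainty band and its effect size over the middle 95% of
#' the exposure's sample; (5) ranks the exposures by effect size.  Walking
#' speed, when requested, is profiled from the gait-pattern model but kept
#' out of the ranking: with no backdoor path requiring adjustment through
#' its descendants its ALE is a direct-effect curve.
#'
#' @param cohort data.frame with (at least) the mapped columns.
#' @param dag the causal model (default [study_dag()]).
#' @param exposures observed exposure variables (DAG names) whose total
#'   effect on `outcome` is wanted.
#' @param outcome outcome variable (DAG name).
#' @param var_map named character vector DAG variable -> cohort column.
#' @param config [bart_config()] used for every model; the default is the
#'   study's selected set (50 trees, k = 5, nu = 3, q = 0.99, missing-data
#'   handling on).
#' @param cv if `TRUE`, hyperparameters are instead selected per model by
#'   [bart_cv()] over `cv_grid`.
#' @param cv_grid grid for `cv` (default [default_bart_grid()]).
#' @param bins ALE quantile bins.
#' @param cutoff plausibility cutoff on |partial r|.
#' @param on_implausible `"warn"` (default) or `"stop"` when the
#'   plausibility check fails.
#' @param include_speed also profile walking speed (direct effect, not
#'   ranked).
#' @param seed master seed; model seeds are derived from it.
#' @return object of class `analysis_report`.
#' @export
run_analysis <- function(cohort, dag = study_dag(),
                         exposures = c("GDI", "DMC", "SMC", "Spasticity",
                                       "Strength"),
                         outcome = "MetPower",
                         var_map = default_var_map,
                         config = bart_config(num_trees = 50L, k = 5, nu = 3,
                                              q = 0.99,
                                              use_missing_data = TRUE),
                         cv = FALSE, cv_grid = NULL, bins = 40L,
                         cutoff = 0.3,
                         on_implausible = c("warn", "stop"),
                         include_speed = FALSE, seed = 42L) {
  on_implausible <- match.arg(on_implausible)
  lookup <- function(v) {
    if (v %in% names(var_map)) var_map[[v]] else v
  }
  need <- vapply(c(exposures, outcome), lookup, character(1L))
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing required column(s): ",
                         paste(miss, collapse = ", "))

  plaus <- test_model_plausibility(dag, cohort, cutoff = cutoff,
                                   var_map = var_map)
  if (plaus$verdict == "fail") {
    msg <- paste0("causal model failed the plausibility check (max |r| = ",
                  format(plaus$max_abs_r, digits = 3), ")")
    if (on_implausible == "stop") stop(msg) else warning(msg)
  }

  # adjustment sets, and one model per distinct {exposure} U set
  adjsets <- list(); skipped <- character()
  predset <- list()
  for (e in exposures) {
    a <- minimal_adjustment_sets(dag, e, outcome)
    adjsets[[e]] <- a
    if (!a$identifiable) { skipped <- c(skipped, e); next }
    predset[[e]] <- sort(unique(c(e, a$sets[[1L]])))
  }
  groups <- split(names(predset),
                  vapply(predset, paste, character(1L), collapse = "|"))
  groups <- groups[order(vapply(groups, `[[`, character(1L), 1L))]

  y <- cohort[[lookup(outcome)]]
  keep <- !is.na(y)
  models <- list(); metrics <- list(); model_of <- character()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    preds <- predset[[members[1L]]]
    cols <- vapply(preds, lookup, character(1L))
    x <- cohort[keep, cols, drop = FALSE]
    names(x) <- preds
    cfg <- config
    if (cv) {
      if (is.null(cv_grid)) {
        cv_grid <- default_bart_grid(
          n_burn = config$n_burn, n_draw = config$n_draw,
          use_missing_data = config$use_missing_data)
      }
      sel <- bart_cv(x, y[keep], cv_grid, seed = seed + 100L + gi)
      cfg <- sel$best
    }
    cfg$seed <- seed + gi
    fit <- bart(x, y[keep], config = cfg)
    name <- paste0("model_", LETTERS[gi])
    models[[name]] <- fit
    metrics[[name]] <- fit_metrics(fit, x, y[keep])
    model_of[members] <- name
  }

  profile <- exposures[!exposures %in% skipped]
  if (include_speed && "Speed" %in% dag$observed) {
    gdi_model <- model_of["GDI"]
    if (!is.na(gdi_model)) model_of["Speed"] <- gdi_model
    profile <- c(profile, "Speed")
  }

  curves <- list(); effects <- list()
  for (e in profile) {
    name <- model_of[[e]]
    fit <- models[[name]]
    cols <- vapply(names(fit$meta$columns), lookup, character(1L))
    x <- cohort[keep, cols, drop = FALSE]
    names(x) <- names(fit$meta$columns)
    cv_curve <- ale_uncertainty(fit, x, e, bins = bins)
    curves[[e]] <- cv_curve
    effects[[e]] <- effect_size(cv_curve)
  }

  ranked_on <- intersect(exposures, names(effects))
  ranking <- data.frame(
    exposure = ranked_on,
    model = unname(model_of[ranked_on]),
    effect_w = vapply(effects[ranked_on], `[[`, numeric(1L), "effect"),
    lower = vapply(effects[ranked_on], function(e)
      if (is.null(e$lower)) NA_real_ else e$lower, numeric(1L)),
    upper = vapply(effects[ranked_on], function(e)
      if (is.null(e$upper)) NA_real_ else e$upper, numeric(1L)),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$effect_w), , drop = FALSE]
  rownames(ranking) <- NULL

  meta <- list(seed = seed, n = nrow(cohort), n_used = sum(keep),
               outcome = outcome, cv = cv,
               config_hash = config_hash(list(config = unclass(config),
                                              bins = bins, cutoff = cutoff,
                                              seed = seed)),
               version = as.character(utils::packageVersion("gaitcausal")),
               timestamp = NULL)
  structure(list(plausibility = plaus, adjustment_sets = adjsets,
                 skipped = skipped, models = models, metrics = metrics,
                 model_of = model_of, curves = curves, effects = effects,
                 ranking = ranking, meta = meta),
            class = "analysis_report")
}

# Stable md5 of a configuration (via its canonical JSON serialization).
config_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== causal analysis report ==\n")
  cat("plausibility:", toupper(x$plausibility$verdict),
      "(max |r| =", format(x$plausibility$max_abs_r, digits = 3),
      "; cutoff", x$plausibility$cutoff, ")\n")
  for (nm in names(x$metrics)) {
    preds <- names(x$models[[nm]]$meta$columns)
    cat(nm, ": predictors {", paste(preds, collapse = ", "), "}  r2 = ",
        format(x$metrics[[nm]]$r2, digits = 3), ", rmse = ",
        format(x$metrics[[nm]]$rmse, digits = 4), "\n", sep = "")
  }
  if (length(x$skipped)) {
    cat("not identifiable by covariate adjustment:",
        paste(x$skipped, collapse = ", "), "\n")
  }
  cat("effect sizes over the middle 95% of each factor (ranked):\n")
  disp <- x$ranking
  disp$effect_w <- round(disp$effect_w, 1)
  disp$lower <- round(disp$lower, 1)
  disp$upper <- round(disp$upper, 1)
  print(disp, row.names = FALSE)
  if ("Speed" %in% names(x$effects)) {
    cat("speed (direct effect, not ranked):",
        round(x$effects$Speed$effect, 1), "W\n")
  }
  cat("seed", x$meta$seed, "| config", substr(x$meta$config_hash, 1, 8),
      "| gaitcausal", x$meta$version, "\n")
  invisible(x)
}

#' Serialize an analysis report
#'
#' @param report an [run_analysis()] result.
#' @param path output file; `.json` for the machine-readable form,
#'   `.md` for the human-readable summary.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(
      meta = report$meta,
      plausibility = list(verdict = report$plausibility$verdict,
                          max_abs_r = report$plausibility$max_abs_r,
                          cutoff = report$plausibility$cutoff,
                          implications = report$plausibility$implications),
      adjustment_sets = lapply(report$adjustment_sets, function(a)
        list(identifiable = a$identifiable, sets = a$sets)),
      metrics = lapply(report$metrics, function(m)
        list(r2 = m$r2, rmse = m$rmse)),
      model_of = as.list(report$model_of),
      effects = lapply(report$effects, function(e)
        list(effect_w = e$effect, window = e$window,
             lower = e$lower, upper = e$upper)),
      ranking = report$ranking)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    lines <- c(
      "# Causal effects on net metabolic power", "",
      paste0("Plausibility: **", report$plausibility$verdict,
             "** (max |partial r| = ",
             format(report$plausibility$max_abs_r, digits = 3), ", cutoff ",
             report$plausibility$cutoff, ")"), "",
      "| exposure | model | effect (W) | 95% interval |",
      "|---|---|---|---|",
      vapply(seq_len(nrow(report$ranking)), function(i) {
        r <- report$ranking[i, ]
        sprintf("| %s | %s | %.1f | (%.1f, %.1f) |", r$exposure, r$model,
                r$effect_w, r$lower, r$upper)
      }, character(1L)), "",
      vapply(names(report$metrics), function(nm)
        sprintf("- %s: r2 = %.2f, rmse = %.2f W", nm,
                report$metrics[[nm]]$r2, report$metrics[[nm]]$rmse),
        character(1L)),
      "",
      paste0("Seed ", report$meta$seed, ", config ",
             report$meta$config_hash, ", gaitcausal ",
             report$meta$version, "."))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands map one-to-one onto package operations: `simulate`
#' (synthetic cohort to CSV), `score` (polychoric-PCA summary scores from
#' an exam table), `validate` (plausibility report), `adjsets` (minimal
#' adjustment sets), `fit` (BART model archive), `ale` (ALE curve CSV),
#' `report` (full pipeline).  Returns the exit status (0 on success)
#' rather than quitting, so it is scriptable and testable; the installed
#' `cli/gaitcausal` script wraps it for shell use.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly: 0 success, 1 runtime error,
#'   2 usage error.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: gaitcausal <simulate|score|validate|adjsets|fit|ale|report> [options]\n",
            "global options: --seed INT --out PATH --bins INT --n INT\n",
            "  simulate --n N --seed S --out DIR\n",
            "  score    --exams FILE --domain D --out FILE\n",
            "  validate --cohort FILE --dag FILE --cutoff C --out FILE\n",
            "  adjsets  --dag FILE --exposure X --outcome Y\n",
            "  fit      --cohort FILE --predictors a,b,c --response y --out FILE\n",
            "  ale      --cohort FILE --model FILE --factor F --bins K --out FILE\n",
            "  report   --cohort FILE [--dag FILE] --seed S --out FILE")
  }
  status <- tryCatch({
    if (!length(args)) { usage(); return(invisible(2L)) }
    cmd <- args[1L]
    opt <- parse_cli_flags(args[-1L])
    switch(
      cmd,
      simulate = {
        cfg <- synthetic_config(n = as.integer(opt_get(opt, "n", 2000)),
                                seed = as.integer(opt_get(opt, "seed", 1)))
        sim <- generate_cohort(cfg)
        write_cohort(sim, opt_get(opt, "out", "."))
        0L
      },
      score = {
        exams <- read_exams(opt_req(opt, "exams"))
        sm <- summary_score(exams, opt_req(opt, "domain"))
        out <- data.frame(id = names(sm$score), score = unname(sm$score))
        utils::write.csv(out, opt_get(opt, "out", stdout()),
                         row.names = FALSE)
        0L
      },
      validate = {
        cohort <- read_cohort(opt_req(opt, "cohort"))
        dag <- if ("dag" %in% names(opt)) read_dag(opt$dag) else study_dag()
        rep <- test_model_plausibility(
          dag, cohort, cutoff = as.numeric(opt_get(opt, "cutoff", 0.3)),
          var_map = default_var_map)
        print(rep)
        if ("out" %in% names(opt)) plausibility_json(rep, opt$out)
        0L
      },
      adjsets = {
        dag <- if ("dag" %in% names(opt)) read_dag(opt$dag) else study_dag()
        a <- minimal_adjustment_sets(dag, opt_req(opt, "exposure"),
                                     opt_req(opt, "outcome"))
        print(a)
        0L
      },
      fit = {
        cohort <- read_cohort(opt_req(opt, "cohort"))
        preds <- strsplit(opt_req(opt, "predictors"), ",")[[1L]]
        yv <- cohort[[opt_req(opt, "response")]]
        keep <- !is.na(yv)
        fit <- bart(cohort[keep, preds, drop = FALSE], yv[keep],
                    config = bart_config(
                      num_trees = 50L, k = 5, nu = 3, q = 0.99,
                      use_missing_data = TRUE,
                      seed = as.integer(opt_get(opt, "seed", 42))))
        bart_archive(fit, opt_req(opt, "out"))
        0L
      },
      ale = {
        cohort <- read_cohort(opt_req(opt, "cohort"))
        model <- bart_restore(opt_req(opt, "model"))
        x <- cohort[names(model$meta$columns)]
        cv_curve <- ale_uncertainty(model, x, opt_req(opt, "factor"),
                                    bins = as.integer(opt_get(opt, "bins", 40)))
        ale_table(list(cv_curve), opt_req(opt, "out"))
        0L
      },
      report = {
        cohort <- read_cohort(opt_req(opt, "cohort"))
        dag <- if ("dag" %in% names(opt)) read_dag(opt$dag) else study_dag()
        rep <- run_analysis(cohort, dag,
                            seed = as.integer(opt_get(opt, "seed", 42)),
                            bins = as.integer(opt_get(opt, "bins", 40)))
        print(rep)
        if ("out" %in% names(opt)) write_report(rep, opt$out)
        0L
      },
      { usage(); 2L })
  },
  usage_error = function(e) { message("error: ", conditionMessage(e)); usage(); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop(structure(class = c("usage_error", "error", "condition"),
                     list(message = paste0("unexpected argument '", a, "'"),
                          call = NULL)))
    }
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE; i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opt
}

opt_get <- function(opt, key, default) {
  if (key %in% names(opt)) opt[[key]] else default
}
opt_req <- function(opt, key) {
  if (!key %in% names(opt)) {
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = paste0("missing required --", key),
                        call = NULL)))
  }
  opt[[key]]
}
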