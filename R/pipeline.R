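# Orchestration and on-disk formats: documented CSV schemas for trial,
# parameter and test-phase tables, a JSON report, and an end-to-end
# pipeline (simulate -> fit -> metrics -> stats -> report) with seeded,
# hash-tracked provenance.

TRIALS_SCHEMA <- c("subject", "t", "target", "mt_ms")
PARAMS_SCHEMA <- c("subject", "A", "tau", "C")
TESTS_SCHEMA <- c("subject", "mt_pre1", "mt_1month")

check_schema <- function(df, required, numeric_cols, what, path = NULL) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, if (!is.null(path)) paste0(" (", path, ")"),
         ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(df))) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(as.character(v)))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad)) {
        stop(what, ": non-numeric `", cl, "` at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      }
      df[[cl]] <- v2
    }
  }
  df
}

#' Read and write the package's CSV and JSON artifacts
#'
#' Trial tables (`subject`, `group`, `side`, `trial`, `t`, `target`,
#' `mt_ms`), subject parameter tables (`subject`, `group`, `A`, `tau`,
#' `C`, `D1`..), test-phase tables (`subject`, `group`, `mt_pre1`,
#' `mt_1month`, `long_term_change`) and the JSON analysis report.
#' Readers validate the documented schema (rejecting malformed rows with
#' row numbers) and preserve unknown columns; write-then-read round-trips
#' are lossless up to numeric printing precision (15 significant digits).
#'
#' @param path File path.
#' @param trials,params,test_phases,report The object to write.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @name reach_io
NULL

write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname reach_io
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, TRIALS_SCHEMA, c("t", "target", "mt_ms", "trial"),
                     "trial table", path)
  validate_trials(df, make_pspec(max(5L, max(df$target))))
  df
}

#' @rdname reach_io
#' @export
write_trials <- function(trials, path) {
  check_schema(trials, TRIALS_SCHEMA, character(), "trial table")
  write_table(trials, path)
}

#' @rdname reach_io
#' @export
read_params <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  dcols <- grep("^D[0-9]+$", names(df), value = TRUE)
  check_schema(df, c(PARAMS_SCHEMA, "D1"), c("A", "tau", "C", dcols),
               "parameter table", path)
}

#' @rdname reach_io
#' @export
write_params <- function(params, path) {
  check_schema(params, c(PARAMS_SCHEMA, "D1"), character(), "parameter table")
  write_table(params, path)
}

#' @rdname reach_io
#' @export
read_test_phases <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, TESTS_SCHEMA, c("mt_pre1", "mt_1month"),
               "test-phase table", path)
}

#' @rdname reach_io
#' @export
write_test_phases <- function(test_phases, path) {
  check_schema(test_phases, TESTS_SCHEMA, character(), "test-phase table")
  write_table(test_phases, path)
}

#' @rdname reach_io
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname reach_io
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# md5 of an object's CSV/JSON text; stable across sessions for identical
# values.
artifact_hash <- function(obj) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  if (is.data.frame(obj)) write.csv(obj, tf, row.names = FALSE)
  else jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  unname(tools::md5sum(tf))
}

#' Demographics of the 26-participant reach-training cohort
#'
#' Per-subject demographics: age, sex, MMSE, affected (stroke) or
#' dominant (control) side, stroke duration in months and baseline
#' upper-extremity Fugl-Meyer score (stroke group only).
#'
#' @return Data frame with one row per participant.
#' @export
read_demographics <- function() {
  path <- system.file("extdata", "demographics.csv", package = "reachnlme",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

# ---- pipeline --------------------------------------------------------------

PIPELINE_STAGES <- c("simulate", "fit", "metrics", "stats")

resolve_cohort_config <- function(x) {
  if (inherits(x, "cohort_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x, stroke = stroke_cohort_config(),
                  control = control_cohort_config(),
                  stop("unknown cohort preset: ", x, call. = FALSE)))
  }
  if (is.list(x)) {
    grp <- x$group %||% "stroke"
    maker <- if (grp == "control") control_cohort_config else
      stroke_cohort_config
    return(do.call(maker, x[setdiff(names(x), "group")]))
  }
  stop("cannot interpret cohort specification", call. = FALSE)
}

validate_run_config <- function(config) {
  stages <- config$stages %||% PIPELINE_STAGES
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)])) {
    stop("`stages` must be a prefix of: ",
         paste(PIPELINE_STAGES, collapse = " -> "), call. = FALSE)
  }
  for (p in c(config$trials, config$test_phases)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes (a prefix of) simulate -> fit -> metrics -> stats and
#' assembles the analysis report: population parameters and group RMSE,
#' per-parameter group contrasts, and the long-term-prediction
#' regressions for both predictors per group. All randomness flows from
#' `config$seed`; identical config and seed give an identical report.
#' When `out_dir` is set, every intermediate is persisted (CSV/JSON) and
#' an expensive stage whose recorded input hashes are unchanged is reused
#' from disk on rerun.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `seed`; `cohorts` (list of `"stroke"`/`"control"` presets,
#'   [cohort_config()]s, or override lists) or `trials`/`test_phases`
#'   (paths to CSV inputs, skipping simulation); `fit` (overrides for
#'   [fit_config()]); `stages` (prefix of the stage list); `out_dir`;
#'   `exclude` (subject ids dropped from the regressions).
#' @return An `analysis_report` list: `provenance`, `population`, `rmse`,
#'   `subjects`, `metrics`, `contrasts`, `long_term`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  seed <- config$seed
  out_dir <- config$out_dir
  manifest_path <- if (!is.null(out_dir)) file.path(out_dir, "manifest.json")
  manifest <- if (!is.null(out_dir) && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  report <- list(provenance = list(
    package = as.character(utils::packageVersion("reachnlme")),
    seed = seed, stages = config$stages
  ))

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs / simulate
  if (!is.null(config$trials)) {
    trials <- run_stage("input", function() read_trials(config$trials))
    test_phases <- if (!is.null(config$test_phases)) {
      read_test_phases(config$test_phases)
    }
    true_params <- NULL
  } else {
    sim <- run_stage("simulate", function() {
      cohorts <- lapply(config$cohorts %||% list("stroke", "control"),
                        resolve_cohort_config)
      simulate_cohort(cohorts, seed = seed)
    })
    trials <- sim$trials
    test_phases <- sim$test_phases
    true_params <- sim$params
  }
  trials_hash <- artifact_hash(trials)
  report$provenance$trials_hash <- trials_hash
  if (!is.null(out_dir)) {
    write_trials(trials, file.path(out_dir, "trials.csv"))
    if (!is.null(test_phases)) {
      write_test_phases(test_phases, file.path(out_dir, "test_phases.csv"))
    }
    if (!is.null(true_params)) {
      write_params(true_params, file.path(out_dir, "generating_params.csv"))
    }
  }
  if (length(config$stages) < 2L) {
    return(finish_report(report, out_dir, manifest))
  }

  # -- fit (reused from disk when inputs unchanged)
  fit_overrides <- config$fit %||% list()
  if (is.null(fit_overrides$seed)) fit_overrides$seed <- seed
  fcfg <- do.call(fit_config, fit_overrides)
  fit_key <- artifact_hash(list(trials = trials_hash,
                                fit = unclass(fcfg)))
  params_path <- if (!is.null(out_dir)) file.path(out_dir, "fitted_params.csv")
  reuse <- !is.null(out_dir) && identical(manifest$fit_key, fit_key) &&
    file.exists(params_path) &&
    file.exists(file.path(out_dir, "fit_summary.json"))
  if (reuse) {
    subjects <- read_params(params_path)
    fit_summary <- jsonlite::read_json(file.path(out_dir, "fit_summary.json"),
                                       simplifyVector = TRUE)
    rmse <- as.data.frame(fit_summary$rmse)
    pop_report <- fit_summary$population
  } else {
    fit <- run_stage("fit", function() fit_nlme(trials, fcfg))
    subjects <- fit$subjects
    rmse <- fit$rmse
    pop_report <- list(
      fixed_effects = as.list(fit$pop$mu),
      random_effect_variances = as.list(fit$pop$omega2),
      residual_sd = fit$pop$sigma,
      natural_medians = list(A = exp(fit$pop$mu[["lA"]]),
                             tau = exp(fit$pop$mu[["ltau"]]))
    )
    if (!is.null(out_dir)) {
      write_params(subjects, params_path)
      write_report(list(population = pop_report, rmse = rmse),
                   file.path(out_dir, "fit_summary.json"))
    }
  }
  manifest$fit_key <- fit_key
  report$population <- pop_report
  report$rmse <- rmse
  report$subjects_hash <- artifact_hash(subjects)
  if (length(config$stages) < 3L) {
    return(finish_report(report, out_dir, manifest))
  }

  # -- metrics
  metrics <- run_stage("metrics", function() {
    derive_metrics(subjects, T = max(trials$t))
  })
  if (!is.null(out_dir)) write_table(metrics, file.path(out_dir, "metrics.csv"))
  report$metrics_hash <- artifact_hash(metrics)
  if (length(config$stages) < 4L) {
    report$metrics <- metrics
    return(finish_report(report, out_dir, manifest))
  }

  # -- stats
  stats_out <- run_stage("stats", function() {
    contrasts <- if (length(unique(subjects$group)) == 2L) {
      contrast_parameters(subjects)
    }
    long_term <- list()
    if (!is.null(test_phases)) {
      for (g in unique(subjects$group)) {
        mg <- metrics[metrics$group == g, ]
        if (nrow(mg) >= 3L) {
          long_term[[g]] <- lapply(
            c(normalized_learning = "normalized_learning",
              normalized_performance_change = "normalized_performance_change"),
            function(pred) {
              res <- predict_long_term(mg, test_phases, predictor = pred,
                                       exclude = config$exclude)
              res[c("r", "r_squared", "p", "n", "slope", "intercept")]
            })
        }
      }
    }
    list(contrasts = contrasts, long_term = long_term)
  })
  report$contrasts <- stats_out$contrasts
  report$long_term <- stats_out$long_term
  report$metrics <- metrics
  if (!is.null(out_dir) && !is.null(stats_out$contrasts)) {
    write_table(stats_out$contrasts, file.path(out_dir, "contrasts.csv"))
  }
  finish_report(report, out_dir, manifest)
}

finish_report <- function(report, out_dir, manifest) {
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    write_report(unclass(report), file.path(out_dir, "report.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Reach-training analysis report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$rmse)) {
    cat("RMSE (ms):\n")
    print(x$rmse, row.names = FALSE)
  }
  if (!is.null(x$contrasts)) {
    cat("group contrasts (p):\n")
    print(setNames(round(x$contrasts$p, 4), x$contrasts$parameter))
  }
  if (length(x$long_term)) {
    for (g in names(x$long_term)) {
      lt <- x$long_term[[g]]
      cat(sprintf("%s: R2(norm. learning) = %.2f, R2(norm. perf. change) = %.2f\n",
                  g, lt$normalized_learning$r_squared,
                  lt$normalized_performance_change$r_squared))
    }
  }
  invisible(x)
}
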