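# End-to-end orchestration: permutation test -> SR-GP LOO-CV -> importance ->
# seven-measure suite -> baseline bench -> statistical validation, with a
# reproducible report.

#' Pipeline configuration
#'
#' Bundles every stage's settings. The defaults reproduce the procedure
#' counts of the study design: four evolution species per cross-validation
#' fold, ten consecutive LOO-CV trials, an 8%-20% suitable-model selection
#' band, a 5% dominance threshold, and 5000 permutations.
#'
#' @param cohort_csv Optional path to a cohort CSV (see [load_cohort()]).
#' @param schema Optional schema (or path to a schema JSON) for the CSV.
#' @param synthetic Optional [synthetic_spec()] used when no CSV is given.
#' @param gp A [gp_config()] for the evolutionary runs.
#' @param species Evolution species per fold.
#' @param trials Consecutive LOO-CV trials.
#' @param selection_band Two fractions `(low, high)` for suitable-model
#'   selection.
#' @param dominance_threshold Frequency percentage above which a variable is
#'   dominant.
#' @param perm_B Permutation count for the preprocessing test.
#' @param perm_classifier Classifier for the permutation test.
#' @param trim_fraction Trimmed-mean fraction for ensembles.
#' @param linear_top_k Terms in the linear validation models (the continuous
#'   target frees the events-per-variable constraint; default 8).
#' @param seed Master seed; every random draw in the run derives from it.
#' @param run_permutation,run_bench,run_suite Stage toggles.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_csv = NULL, schema = NULL, synthetic = NULL,
                            gp = gp_config(), species = 4, trials = 10,
                            selection_band = c(0.08, 0.20),
                            dominance_threshold = 5, perm_B = 5000,
                            perm_classifier = "rf", trim_fraction = 0.1,
                            linear_top_k = 8, seed = 1,
                            run_permutation = TRUE, run_bench = TRUE,
                            run_suite = TRUE) {
  structure(list(cohort_csv = cohort_csv, schema = schema,
                 synthetic = synthetic, gp = gp, species = species,
                 trials = trials, selection_band = selection_band,
                 dominance_threshold = dominance_threshold, perm_B = perm_B,
                 perm_classifier = perm_classifier,
                 trim_fraction = trim_fraction, linear_top_k = linear_top_k,
                 seed = as.integer(seed), run_permutation = run_permutation,
                 run_bench = run_bench, run_suite = run_suite),
            class = "pipeline_config")
}

pipeline_cohort <- function(config) {
  if (!is.null(config$cohort_csv)) {
    schema <- config$schema
    if (is.character(schema)) schema <- read_schema(schema)
    load_cohort(config$cohort_csv, schema)
  } else {
    spec <- config$synthetic %||% synthetic_spec(seed = derive_seed(config$seed, 11))
    generate_cohort(spec)$cohort
  }
}

#' Run the full pipeline
#'
#' Executes, in order: cohort loading/generation and imputation, the
#' permutation preprocessing test, LOO-CV symbolic regression (best of
#' `trials` by pooled AUC), suitable-model selection and the
#' frequency/ML-score table with dominant variables, the seven-measure
#' importance suite, the nine-learner benchmark, and the statistical
#' validation: multivariable logistic models on the ML-top-k versus
#' |r|-top-k variables with k set by the five-events-per-variable rule, and
#' linear models on the top `linear_top_k` variables of both rankings with
#' VIF diagnostics. A failing stage is recorded in the report's error
#' manifest and the remaining stages still run.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, an already-built `srg_cohort` (overrides the
#'   config's data source).
#' @param out_dir Optional directory; when given, CSV tables and a JSON run
#'   manifest (with all derived seeds) are written there.
#' @return An `srg_report` list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (is.null(cohort)) cohort <- pipeline_cohort(config)
  cohort <- impute_missing(cohort)
  vars <- names(cohort$predictors)
  report <- list(config = config, n = nrow(cohort$predictors),
                 p = length(vars),
                 prevalence = mean(cohort$gh_label))

  report$group_compare <- stage("group_compare", group_compare(cohort))

  if (config$run_permutation) {
    report$permutation <- stage("permutation", permutation_test(
      cohort, classifier = config$perm_classifier, B = config$perm_B,
      seed = derive_seed(config$seed, 21)))
  }

  gp_cfg <- config$gp
  gp_cfg$seed <- derive_seed(config$seed, 31)
  report$cv <- stage("loo_cv", loo_cv_srgp(cohort, gp_cfg,
                                           species = config$species,
                                           trials = config$trials,
                                           trim_fraction = config$trim_fraction))

  if (!is.null(report$cv)) {
    report$importance <- stage("importance", importance_table(
      report$cv$archive, vars, config$selection_band[1],
      config$selection_band[2]))
    if (!is.null(report$importance)) {
      freq <- stats::setNames(report$importance$frequency,
                              report$importance$variable)
      report$dominant <- dominant_variables(freq, config$dominance_threshold)
    }
  }

  if (config$run_suite && !is.null(report$importance)) {
    ml <- stats::setNames(report$importance$ml_score, report$importance$variable)
    report$suite <- stage("suite", importance_suite(
      cohort, ml, seed = derive_seed(config$seed, 41)))
  }

  if (config$run_bench) {
    report$bench <- stage("bench", baseline_bench(
      cohort, seed = derive_seed(config$seed, 51), gp_config = config$gp,
      trim_fraction = config$trim_fraction))
  }

  report$validation <- stage("validation", {
    corr <- correlation_ranking(cohort)
    npos <- sum(cohort$gh_label)
    k_log <- max(1, floor(npos / 5))
    ml_order <- report$importance$variable
    r_order <- corr$variable
    k_lin <- min(config$linear_top_k, length(vars))
    list(
      correlation = corr,
      k_logistic = k_log,
      logistic_ml = fit_logistic(cohort, ml_order[seq_len(k_log)]),
      logistic_r = fit_logistic(cohort, r_order[seq_len(k_log)]),
      linear_ml = fit_linear(cohort, ml_order[seq_len(k_lin)]),
      linear_r = fit_linear(cohort, r_order[seq_len(k_lin)]))
  })

  report$errors <- errors
  class(report) <- "srg_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.srg_report <- function(x, ...) {
  cat(sprintf("srg_report: %d x %d cohort, prevalence %.1f%%\n",
              x$n, x$p, 100 * x$prevalence))
  if (!is.null(x$permutation)) print(x$permutation)
  if (!is.null(x$cv)) print(x$cv$metrics)
  if (!is.null(x$dominant)) {
    cat("dominant variables:", paste(x$dominant, collapse = ", "), "\n")
  }
  if (!is.null(x$validation)) {
    cat(sprintf("logistic (ML top %d): pseudo-R2 %.2f, C %.2f | (|r| top %d): pseudo-R2 %.2f, C %.2f\n",
                x$validation$k_logistic, x$validation$logistic_ml$pseudo_r2,
                x$validation$logistic_ml$c_statistic, x$validation$k_logistic,
                x$validation$logistic_r$pseudo_r2,
                x$validation$logistic_r$c_statistic))
    cat(sprintf("linear (ML top %d): R2 %.2f, max VIF %.2f | (|r| top %d): R2 %.2f, max VIF %.2f\n",
                length(x$validation$linear_ml$terms), x$validation$linear_ml$r2,
                max(x$validation$linear_ml$vif),
                length(x$validation$linear_r$terms), x$validation$linear_r$r2,
                max(x$validation$linear_r$vif)))
  }
  if (length(x$errors)) {
    cat("stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

fmt_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 12, trim = TRUE)
  }
  df
}

write_table_csv <- function(df, path) {
  utils::write.table(fmt_num_df(df), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
}

fit_to_rows <- function(fit) {
  if (inherits(fit, "srg_logit")) {
    data.frame(term = fit$terms,
               odds_ratio = fit$odds_ratio[-1],
               ci_low = fit$or_ci_low[-1], ci_high = fit$or_ci_high[-1],
               p_value = fit$p_value[-1])
  } else {
    data.frame(term = fit$terms, std_beta = fit$std_beta, vif = fit$vif,
               t_ratio = fit$t_ratio, p_value = fit$p_value)
  }
}

#' Write a pipeline report to disk
#'
#' Emits one CSV per result table plus `manifest.json` carrying the master
#' seed, stage settings, scalar statistics, and the error manifest. Output
#' is byte-identical across runs with the same configuration and seed.
#'
#' @param report An `srg_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir` invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  if (!is.null(report$group_compare)) {
    write_table_csv(report$group_compare, pth("group_compare.csv"))
  }
  if (!is.null(report$importance)) {
    write_table_csv(as.data.frame(report$importance), pth("importance.csv"))
  }
  if (!is.null(report$suite)) write_table_csv(report$suite, pth("importance_suite.csv"))
  if (!is.null(report$bench)) write_table_csv(report$bench, pth("bench.csv"))
  if (!is.null(report$validation)) {
    v <- report$validation
    write_table_csv(v$correlation, pth("correlation_ranking.csv"))
    write_table_csv(fit_to_rows(v$logistic_ml), pth("logistic_ml.csv"))
    write_table_csv(fit_to_rows(v$logistic_r), pth("logistic_r.csv"))
    write_table_csv(fit_to_rows(v$linear_ml), pth("linear_ml.csv"))
    write_table_csv(fit_to_rows(v$linear_r), pth("linear_r.csv"))
  }
  manifest <- list(
    seed = report$config$seed,
    n = report$n, p = report$p, prevalence = report$prevalence,
    species = report$config$species, trials = report$config$trials,
    selection_band = report$config$selection_band,
    dominance_threshold = report$config$dominance_threshold,
    perm_B = report$config$perm_B,
    derived_seeds = list(synthetic = derive_seed(report$config$seed, 11),
                         permutation = derive_seed(report$config$seed, 21),
                         gp = derive_seed(report$config$seed, 31),
                         suite = derive_seed(report$config$seed, 41),
                         bench = derive_seed(report$config$seed, 51)),
    permutation = if (!is.null(report$permutation)) {
      list(observed = report$permutation$observed_score,
           p_value = report$permutation$p_value)
    },
    cv = if (!is.null(report$cv)) {
      list(trial = report$cv$trial, trial_aucs = report$cv$trial_aucs,
           metrics = unclass(report$cv$metrics))
    },
    dominant = report$dominant,
    validation = if (!is.null(report$validation)) {
      v <- report$validation
      list(k_logistic = v$k_logistic,
           logistic_ml = list(pseudo_r2 = v$logistic_ml$pseudo_r2,
                              aicc = v$logistic_ml$aicc,
                              c_statistic = v$logistic_ml$c_statistic),
           logistic_r = list(pseudo_r2 = v$logistic_r$pseudo_r2,
                             aicc = v$logistic_r$aicc,
                             c_statistic = v$logistic_r$c_statistic),
           linear_ml = list(r2 = v$linear_ml$r2, aicc = v$linear_ml$aicc,
                            max_vif = max(v$linear_ml$vif)),
           linear_r = list(r2 = v$linear_r$r2, aicc = v$linear_r$aicc,
                           max_vif = max(v$linear_r$vif)))
    },
    errors = report$errors)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(out_dir)
}
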