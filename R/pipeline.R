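# End-to-end orchestration: simulate -> metrics -> densities -> criteria ->
# incidence / model -> report.

#' Run the full CGM risk analysis on a cohort and its traces
#'
#' Stages, in order: wear-time quality filtering ([filter_complete_days()]),
#' time-in-range metrics ([compute_time_in_ranges()]), clinical annotation
#' ([add_clinical_flags()]), baseline group comparisons, glucodensity
#' estimation and the barycenter permutation test, incidence estimation
#' ([poisson_rate_ci()]) and the adjusted logistic model
#' ([fit_risk_model()]).  Any stage failure aborts with a stage-named error.
#'
#' @param cohort Cohort tibble (see [read_cohort_csv()] for the schema).
#' @param traces Long-format CGM trace tibble for the cohort's subjects.
#' @param completeness_fraction,min_days Wear-day quality rule (defaults
#'   0.8 and 2).
#' @param n_permutations Permutations for the glucodensity test.
#' @param horizon_years,progressor_year_fraction Person-time bookkeeping for
#'   the incidence rate.
#' @param seed Integer seed used for the permutation test.
#' @return A `cgmrisk_report` list: `wear_table`, `eligible_ids`,
#'   `metrics`, `baseline_table`, `range_table`, `incidence`, `fit`,
#'   `density_test`, `manifest`.
#' @export
analyze_study <- function(cohort, traces, completeness_fraction = 0.8,
                          min_days = 2L, n_permutations = 999L,
                          horizon_years = 5, progressor_year_fraction = 0.5,
                          seed = 1L) {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)))
    })
  }
  cohort <- run_stage("cohort_schema", {
    needed <- c("subject_id", "age", "sex", "family_history_dm", "bmi",
                "fpg", "hba1c", "outcome_t2d_5y")
    missing_cols <- setdiff(needed, names(cohort))
    if (length(missing_cols)) {
      abort(paste0("cohort is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    tibble::as_tibble(cohort)
  })
  filtered <- run_stage("wear_filter",
                        filter_complete_days(traces, completeness_fraction,
                                             min_days))
  wear <- attr(filtered, "wear")
  eligible_ids <- wear$subject_id[wear$eligible]
  if (!length(eligible_ids)) abort("stage `wear_filter` failed: no eligible subjects")
  filtered <- filtered[filtered$subject_id %in% eligible_ids, ]
  metrics <- run_stage("range_metrics", compute_time_in_ranges(filtered))

  analysed <- run_stage("clinical_flags", {
    x <- dplyr::inner_join(cohort, metrics, by = "subject_id")
    if (all(c("waist", "triglycerides", "hdl", "sbp", "dbp",
              "antihypertensive_use", "fasting_insulin") %in% names(x))) {
      add_clinical_flags(x)
    } else {
      x
    }
  })
  outcome <- as.logical(analysed$outcome_t2d_5y)

  baseline_vars <- c(age = "mannwhitney", bmi = "mannwhitney",
                     fpg = "mannwhitney", hba1c = "mannwhitney")
  names(baseline_vars) <- c("age", "bmi", "fpg", "hba1c")
  extra <- c(family_history_dm = "chisq", metabolic_syndrome = "chisq",
             abdominal_obesity = "chisq", high_bp = "chisq")
  baseline_vars <- c(baseline_vars, extra[names(extra) %in% names(analysed)])
  baseline_table <- run_stage("baseline_table",
                              compare_groups(analysed, "outcome_t2d_5y",
                                             baseline_vars))
  range_table <- run_stage("range_table",
                           compare_groups(analysed, "outcome_t2d_5y",
                                          c(tbr_pct = "mannwhitney",
                                            tir_pct = "mannwhitney",
                                            tar_pct = "mannwhitney")))

  incidence <- run_stage("incidence", {
    ev <- sum(outcome)
    n <- nrow(analysed)
    poisson_rate_ci(ev, person_years_fixed_horizon(n, ev, horizon_years,
                                                   progressor_year_fraction),
                    n_at_risk = n)
  })

  fit <- run_stage("risk_model", fit_risk_model(analysed))

  density_test <- run_stage("glucodensity_test", {
    dens <- estimate_glucodensities(filtered)
    dens <- dplyr::inner_join(dens, analysed[, c("subject_id", "outcome_t2d_5y")],
                              by = "subject_id")
    permutation_mean_test(dens[as.logical(dens$outcome_t2d_5y), ],
                          dens[!as.logical(dens$outcome_t2d_5y), ],
                          n_permutations = n_permutations, seed = seed)
  })

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("cgmrisk")),
    n_input_subjects = dplyr::n_distinct(cohort$subject_id),
    n_analysed = nrow(analysed),
    completeness_fraction = completeness_fraction, min_days = min_days,
    n_permutations = n_permutations,
    horizon_years = horizon_years,
    progressor_year_fraction = progressor_year_fraction,
    input_hash = rlang::hash(list(cohort, traces))
  )
  structure(
    list(wear_table = wear, eligible_ids = eligible_ids, metrics = metrics,
         baseline_table = baseline_table, range_table = range_table,
         incidence = incidence, fit = fit, density_test = density_test,
         analysed = analysed, manifest = manifest),
    class = "cgmrisk_report"
  )
}

#' Simulate a study end-to-end and analyse it
#'
#' Generates a matched-moments cohort and its CGM traces from `config`,
#' then runs [analyze_study()] on them.  Stage seeds are fanned out
#' deterministically from the single configured seed.
#'
#' @param config A [cohort_config()] with a seed.
#' @param ... Passed on to [analyze_study()].
#' @return A `cgmrisk_report`; the simulated `cohort` and `traces` are
#'   attached as elements.
#' @export
simulate_study <- function(config, ...) {
  stopifnot(inherits(config, "cgm_cohort_config"))
  if (is.null(config$seed)) abort("simulate mode requires a seed in the config")
  cohort <- generate_cohort(config)
  traces <- generate_cgm_traces(cohort, config, seed = child_seed(config$seed, 1e6))
  report <- analyze_study(cohort, traces, seed = child_seed(config$seed, 2e6), ...)
  report$cohort <- cohort
  report$traces <- traces
  report$manifest$config_hash <- rlang::hash(unclass(config))
  report$manifest$seed <- config$seed
  report
}

#' Run the pipeline from a configuration
#'
#' Thin orchestration entry point: in `"simulate"` mode generates and
#' analyses a synthetic study; in `"analyze"` mode reads a cohort CSV and a
#' trace CSV and analyses them.  When `out_dir` is given all report
#' artifacts are written there with [write_report_bundle()].
#'
#' @param mode `"simulate"` or `"analyze"`.
#' @param config A [cohort_config()] (simulate mode).
#' @param cohort_csv,cgm_csv Input paths (analyze mode).
#' @param out_dir Optional output directory.
#' @param ... Passed to [analyze_study()].
#' @return A `cgmrisk_report`.
#' @export
run_pipeline <- function(mode = c("simulate", "analyze"), config = NULL,
                         cohort_csv = NULL, cgm_csv = NULL, out_dir = NULL,
                         ...) {
  mode <- match.arg(mode)
  report <- if (mode == "simulate") {
    if (is.null(config)) abort("simulate mode needs `config`")
    simulate_study(config, ...)
  } else {
    if (is.null(cohort_csv) || is.null(cgm_csv)) {
      abort("analyze mode needs `cohort_csv` and `cgm_csv`")
    }
    if (!file.exists(cohort_csv)) abort(paste0("no such file: ", cohort_csv))
    if (!file.exists(cgm_csv)) abort(paste0("no such file: ", cgm_csv))
    analyze_study(read_cohort_csv(cohort_csv), read_cgm_csv(cgm_csv), ...)
  }
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Writes the wear-time, baseline and range tables (TSV), the per-subject
#' metrics (CSV), the incidence summary, model summary, density test result
#' and run manifest (JSON) into `dir`.
#'
#' @param report A `cgmrisk_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "cgmrisk_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$wear_table, file.path(dir, "wear_table.tsv"))
  readr::write_tsv(report$baseline_table, file.path(dir, "baseline_table.tsv"))
  readr::write_tsv(report$range_table, file.path(dir, "range_table.tsv"))
  readr::write_csv(report$metrics, file.path(dir, "range_metrics.csv"))
  jsonlite::write_json(report$incidence, file.path(dir, "incidence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  model_summary <- list(
    coefficients = tidy(report$fit),
    auc = report$fit$auc, auc_ci = report$fit$auc_ci,
    brier = report$fit$brier, n = report$fit$n, events = report$fit$events
  )
  jsonlite::write_json(model_summary, file.path(dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  dt <- report$density_test
  jsonlite::write_json(
    list(observed_statistic = dt$observed_statistic, p_value = dt$p_value,
         n_permutations = dt$n_permutations, seed = dt$seed),
    file.path(dir, "density_test.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$cohort)) {
    write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
  }
  if (!is.null(report$traces)) {
    write_cgm_csv(report$traces, file.path(dir, "traces.csv"))
  }
  invisible(dir)
}

#' @export
print.cgmrisk_report <- function(x, ...) {
  cat("CGM diabetes-risk analysis report\n")
  cat(sprintf("  analysed subjects: %d (%d eligible of %d input)\n",
              x$manifest$n_analysed, length(x$eligible_ids),
              x$manifest$n_input_subjects))
  inc <- x$incidence
  cat(sprintf("  cumulative incidence: %s%%; rate %s/1,000 PY (95%% CI %s-%s)\n",
              fmt1(inc$cumulative_incidence_pct), fmt1(inc$rate_per_1000py),
              fmt1(inc$ci_lo), fmt1(inc$ci_hi)))
  cat(sprintf("  glucodensity permutation test: p = %.3g\n",
              x$density_test$p_value))
  print(x$fit)
  invisible(x)
}
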