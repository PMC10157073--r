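#' Build a run configuration
#'
#' Collects every knob of the end-to-end analysis into one validated list.
#' A persisted configuration plus its inputs determines all outputs: the
#' single master seed is expanded deterministically into per-stage seeds.
#'
#' @param features path to a feature CSV/TSV, or a [feature_table()], or
#'   `NULL` to simulate the default synthetic cohort.
#' @param covariates path to a covariate table, a [covariate_table()], or
#'   `NULL`.
#' @param label_column label column name used when reading from file.
#' @param outer_k,outer_repeats,inner_k,inner_repeats cross-validation plan.
#' @param C_grid penalty grid.
#' @param n_perm permutations for the significance test (0 skips it).
#' @param prevalences assumed prevalence rates for the predictive-value sweep.
#' @param printed_rounding use one-percentage-decimal pre-rounding in the sweep.
#' @param seed master seed.
#' @param out_dir output directory for CSV tables and the JSON manifest
#'   (`NULL` returns results without writing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(features = NULL, covariates = NULL, label_column = "group",
                       outer_k = 10, outer_repeats = 10,
                       inner_k = 10, inner_repeats = 10,
                       C_grid = default_C_grid(), n_perm = 0,
                       prevalences = c(0.01, 0.05, 0.10, 0.20, 0.30, 0.40,
                                       0.50, 0.60, 0.70),
                       printed_rounding = FALSE, seed = 1, out_dir = NULL) {
  for (p in list(features, covariates)) {
    if (is.character(p) && !file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(list(features = features, covariates = covariates,
                 label_column = label_column,
                 outer_k = outer_k, outer_repeats = outer_repeats,
                 inner_k = inner_k, inner_repeats = inner_repeats,
                 C_grid = C_grid, n_perm = n_perm, prevalences = prevalences,
                 printed_rounding = printed_rounding,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; recognized keys match [run_config()]
#'   arguments.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stopf("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: load or simulate the cohort, run the
#' repeated nested cross-validation, compute confusion/prevalence metrics,
#' the feature-stability map, the univariate group screen, the optional
#' permutation test, and (when covariates are available) the post-hoc
#' stepwise regression of decision scores. When `out_dir` is set, each table
#' is written as CSV in its canonical column order plus a JSON run manifest
#' with seeds and warnings.
#'
#' @param config a [run_config()].
#' @return A list bundle: `result` (nested CV), `metrics`, `prevalence_table`,
#'   `stability`, `group_stats`, `permutation` (or `NULL`), `stepwise` (or
#'   `NULL`), `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  log_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  seeds <- list(simulate = derive_seed(config$seed, 11L),
                cv = derive_seed(config$seed, 12L),
                perm = derive_seed(config$seed, 13L))

  cov <- NULL
  if (is.null(config$features)) {
    cohort <- generate_cohort(synthetic_spec(seed = seeds$simulate))
    ft <- cohort$features
    cov <- cohort$covariates
  } else if (inherits(config$features, "feature_table")) {
    ft <- config$features
  } else {
    ft <- read_feature_table(config$features, label_column = config$label_column)
  }
  if (!is.null(config$covariates)) {
    cov <- if (inherits(config$covariates, "covariate_table")) config$covariates else
      read_covariate_table(config$covariates)
  }

  res <- log_warnings(run_nested_cv(
    ft, outer_k = config$outer_k, outer_repeats = config$outer_repeats,
    inner_k = config$inner_k, inner_repeats = config$inner_repeats,
    C_grid = config$C_grid, seed = seeds$cv))
  cs <- res$confusion
  metrics <- data.frame(tp = cs$tp, tn = cs$tn, fp = cs$fp, fn = cs$fn,
                        sens_pct = round_half_up(100 * cs$sens, 1),
                        spec_pct = round_half_up(100 * cs$spec, 1),
                        bac_pct = round_half_up(100 * cs$bac, 1),
                        ppv_pct = round_half_up(100 * cs$ppv, 1),
                        npv_pct = round_half_up(100 * cs$npv, 1),
                        nnd = round_half_up(cs$nnd, 2),
                        psi = round_half_up(cs$psi, 3),
                        auc = round_half_up(cs$auc, 2))
  sweep <- prevalence_sweep(cs$sens, cs$spec, config$prevalences,
                            printed_rounding = config$printed_rounding)
  prevalence_table <- format_prevalence_table(sweep)
  stability <- log_warnings(feature_stability(res))
  group_stats <- group_screen(ft)
  permutation <- NULL
  if (config$n_perm > 0) {
    permutation <- permutation_test(
      ft, n_perm = config$n_perm, seed = seeds$perm,
      outer_k = config$outer_k, outer_repeats = config$outer_repeats,
      inner_k = config$inner_k, inner_repeats = config$inner_repeats,
      C_grid = config$C_grid)
  }
  stepwise <- NULL
  if (!is.null(cov)) {
    inputs <- log_warnings(assemble_posthoc_inputs(res, cov, subset = "positive"))
    stepwise <- log_warnings(stepwise_fit(inputs$response, inputs$candidates))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("dtipattern")),
                   master_seed = config$seed, stage_seeds = seeds,
                   n_subjects = length(res$mean_scores),
                   n_features = length(ft$feature_names),
                   n_ensemble_members = length(res$ensemble$members),
                   warnings = warnings_log)

  bundle <- list(result = res, metrics = metrics,
                 prevalence_table = prevalence_table, stability = stability,
                 group_stats = group_stats, permutation = permutation,
                 stepwise = stepwise, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) utils::write.csv(df, file.path(config$out_dir, name),
                                              row.names = FALSE)
    wr(metrics, "metrics.csv")
    wr(prevalence_table, "prevalence.csv")
    wr(stability, "stability.csv")
    wr(group_stats, "group_stats.csv")
    wr(data.frame(subject_id = res$subject_ids, label = res$labels,
                  mean_score = res$mean_scores, prediction = res$predictions),
       "scores.csv")
    if (!is.null(stepwise)) wr(stepwise$coefficients, "stepwise.csv")
    if (!is.null(permutation)) {
      manifest$permutation_p <- permutation$p_value
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
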