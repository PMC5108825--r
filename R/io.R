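#' Read and write cohort CSV files
#'
#' The interchange format is plain CSV with header
#' `id,age,bmi,psa,case_status` plus any optional columns (`diabetes`,
#' `height_missing`, `true_cancer`, adjusted-PSA columns). The reader
#' validates the table and reports the file, line and column of the first
#' problem it finds.
#'
#' @param path File path.
#' @return `read_cohort()`: a validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "bmi", "psa", "case_status")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (col in c("age", "bmi", "psa", "case_status")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s: line %d, column '%s': non-numeric value '%s'",
                   path, bad + 1L, col, v[bad]))
    }
    if (anyNA(v))
      stop(sprintf("%s: line %d, column '%s': missing value",
                   path, which(is.na(v))[1] + 1L, col))
  }
  if (!all(d$case_status %in% c(0, 1))) {
    bad <- which(!d$case_status %in% c(0, 1))[1]
    stop(sprintf("%s: line %d, column 'case_status': value must be 0 or 1",
                 path, bad + 1L))
  }
  d
}

#' @rdname read_cohort
#' @param cohort Cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted PSA model as CSV
#'
#' Writes one row per term: coefficient, SE, 95% CI and (for age/BMI) the
#' per-5-unit percentage change.
#'
#' @param fit A `psa_fit` object.
#' @param path Output file.
#' @export
write_fit <- function(fit, path) {
  tab <- fit$coefficients
  tab$percent_change_per_5 <-
    ifelse(tab$term %in% c("age", "bmi"),
           percent_change_per_5(tab$estimate), NA)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML file whose keys mirror [cohort_config()] arguments plus the
#' run-level blocks used by [run_pipeline()] (`seed`, `out_dir`,
#' `thresholds`, `biopsy_sensitivity`). Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c(names(formals(cohort_config)),
               "out_dir", "thresholds", "biopsy_sensitivity")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end under a single seed: simulate a cohort,
#' apply the inclusion filters, fit the univariable and multivariable
#' log-PSA models, append adjusted PSAs, evaluate all models at the fixed
#' thresholds and the NICE age bands (including the matched-specificity
#' comparison with McNemar's test), run tenfold cross-validation, and
#' tabulate the verification-bias example. Per-stage seeds are derived
#' deterministically from the top-level seed so stages are independently
#' re-runnable; rerunning with the same seed reproduces every artifact
#' byte for byte.
#'
#' @param config Optional list from [read_run_config()] with
#'   [cohort_config()] overrides and run settings.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level integer seed.
#' @param verbose Print progress?
#' @return Invisibly, a named list of the artifact file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = "results",
                         seed = 1L, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  thresholds <- config$thresholds
  if (is.null(thresholds)) thresholds <- c(3.0, 4.0)
  gen_args <- config[names(config) %in% names(formals(cohort_config))]
  gen_args$seed <- seed
  cfg <- do.call(cohort_config, gen_args)

  say("simulate: generating cohort")
  cohort <- generate_cohort(cfg)
  filt <- apply_inclusion_filters(cohort,
                                  max_control_psa = cfg$control_max_psa)
  cohort <- filt$cohort
  paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                exclusions = file.path(out_dir, "exclusions.csv"),
                fit = file.path(out_dir, "fit_multivariable.csv"),
                cohort_adjusted = file.path(out_dir, "cohort_adjusted.csv"),
                evaluation = file.path(out_dir, "evaluation.csv"),
                matched = file.path(out_dir, "matched_specificity.csv"),
                cv = file.path(out_dir, "cv.csv"),
                interaction = file.path(out_dir, "interaction.csv"),
                bias = file.path(out_dir, "bias_apparent_vs_true.csv"))
  write_cohort(cohort, paths$cohort)
  utils::write.csv(filt$exclusions, paths$exclusions, row.names = FALSE,
                   quote = FALSE)

  say("fit: log-linear PSA models")
  adj <- add_adjusted_psa(cohort)
  write_fit(attr(adj, "fits")$age_bmi, paths$fit)
  write_cohort(adj, paths$cohort_adjusted)

  say("evaluate: thresholds and NICE rule")
  score_cols <- c(observed = "psa", age = "psa_adj_age",
                  bmi = "psa_adj_bmi", age_bmi = "psa_adj_age_bmi")
  rules <- c(lapply(thresholds, fixed_rule), list(nice_rule()))
  utils::write.csv(evaluate_thresholds(adj, score_cols, rules),
                   paths$evaluation, row.names = FALSE, quote = FALSE)

  nice_spec <- sens_spec(classify(adj, "psa", nice_rule()))$specificity
  matched <- do.call(rbind, lapply(names(score_cols), function(m) {
    ms <- matched_specificity_sensitivity(adj, score_cols[[m]], nice_spec)
    mc <- mcnemar_compare(adj, score_cols[[m]], fixed_rule(ms$threshold),
                          "psa", nice_rule())
    data.frame(model = m, threshold = ms$threshold,
               achieved_specificity = ms$achieved_specificity,
               sensitivity = ms$sensitivity, mcnemar_b = mc$b,
               mcnemar_c = mc$c, mcnemar_p = mc$p_value,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(matched, paths$matched, row.names = FALSE, quote = FALSE)

  say("cv: tenfold cross-validation")
  cv <- tenfold_cv(adj, rules = rules, seed = seed + 1L)
  utils::write.csv(cv$summary, paths$cv, row.names = FALSE, quote = FALSE)
  utils::write.csv(interaction_test(adj), paths$interaction,
                   row.names = FALSE, quote = FALSE)

  say("bias: apparent vs true accuracy")
  lat_cfg_args <- gen_args
  lat_cfg_args$latent_truth <- TRUE
  lat_cfg_args$seed <- seed + 2L
  lat <- generate_cohort(do.call(cohort_config, lat_cfg_args))
  bsens <- config$biopsy_sensitivity
  if (is.null(bsens)) bsens <- 0.85
  truth <- simulate_verification(lat, biopsy_cutoff = 3.0,
                                 biopsy_sensitivity = bsens,
                                 seed = seed + 3L)
  avt <- apparent_vs_true(truth)
  utils::write.csv(
    data.frame(metric = c("sensitivity", "specificity"),
               apparent = c(avt$apparent$sensitivity,
                            avt$apparent$specificity),
               true = c(avt$true$sensitivity, avt$true$specificity),
               bias = c(avt$bias$sensitivity, avt$bias$specificity)),
    paths$bias, row.names = FALSE, quote = FALSE)
  say("done: artifacts in ", out_dir)
  invisible(paths)
}
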