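#' Stratified fold assignment
#'
#' Randomly assigns each subject to one of `k` folds, stratified by case
#' status so that every fold carries its share of cases: within each
#' stratum fold sizes differ by at most one.
#'
#' @param case_status 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k).
#' @export
make_folds <- function(case_status, k = 10L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(case_status))
  for (s in unique(case_status)) {
    idx <- which(case_status == s)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tenfold cross-validated accuracy of PSA models
#'
#' For each fold, the adjustment models are fitted on the other nine folds,
#' adjusted PSAs are computed for the held-out fold using the training
#' coefficients and training-sample reference means, and sensitivity and
#' specificity are evaluated there for every model-by-rule combination. The
#' `"observed"` model uses raw PSA and involves no fitting (so rules such
#' as the NICE age bands are simply re-evaluated per fold).
#'
#' @param cohort Cohort `data.frame`.
#' @param models Character vector from
#'   `c("observed", "age", "bmi", "age_bmi")`.
#' @param rules Named or unnamed list of `threshold_rule`s.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving the fold assignment.
#' @param include_case_status Passed to the training fits.
#' @return A `cv_result` object: `summary` (per model x rule: mean and SD
#'   of each metric over folds), `folds` (per-fold metrics), `assignment`,
#'   `seed`.
#' @export
tenfold_cv <- function(cohort,
                       models = c("observed", "age", "bmi", "age_bmi"),
                       rules = list(fixed_rule(3), fixed_rule(4)),
                       k = 10L, seed = 1L, include_case_status = TRUE) {
  models <- match.arg(models, c("observed", "age", "bmi", "age_bmi"),
                      several.ok = TRUE)
  fold <- make_folds(cohort$case_status, k = k, seed = seed)
  score_col <- c(observed = "psa", age = "psa_adj_age", bmi = "psa_adj_bmi",
                 age_bmi = "psa_adj_age_bmi")
  rows <- list()
  for (f in seq_len(k)) {
    train <- cohort[fold != f, , drop = FALSE]
    test <- cohort[fold == f, , drop = FALSE]
    if (sum(test$case_status == 1) == 0)
      stop("fold ", f, " has no cases: sensitivity margin empty")
    if (sum(test$case_status == 0) == 0)
      stop("fold ", f, " has no controls: specificity margin empty")
    need_fit <- any(models != "observed")
    if (need_fit) {
      fits <- list(
        age = fit_log_psa(train, "age", include_case_status),
        bmi = fit_log_psa(train, "bmi", include_case_status),
        age_bmi = fit_log_psa(train, c("age", "bmi"), include_case_status))
      test <- add_adjusted_psa(test, fits = fits)
    }
    for (m in models) {
      for (ri in seq_along(rules)) {
        r <- rules[[ri]]
        ss <- sens_spec(classify(test, score_col[[m]], r))
        rows[[length(rows) + 1L]] <-
          data.frame(fold = f, model = m, rule = r$label,
                     sensitivity = ss$sensitivity,
                     specificity = ss$specificity,
                     stringsAsFactors = FALSE)
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  key <- interaction(folds_df$model, folds_df$rule, drop = TRUE)
  summ <- do.call(rbind, lapply(split(folds_df, key), function(d) {
    data.frame(model = d$model[1], rule = d$rule[1],
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = stats::sd(d$sensitivity),
               mean_specificity = mean(d$specificity),
               sd_specificity = stats::sd(d$specificity),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, folds = folds_df, assignment = fold,
                 seed = seed, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Z-test for a coefficient difference between two fits
#'
#' For each covariate, computes
#' \eqn{Z = (\beta_{below} - \beta_{above}) / \sqrt{se_{below}^2 +
#' se_{above}^2}} and a two-sided p-value from the standard normal.
#'
#' @param fit_below,fit_above `psa_fit` objects for the two strata.
#' @param covariates Covariates to compare (present in both fits).
#' @return `data.frame` with per-covariate coefficients, SEs, `z`, `p`.
#' @export
coef_diff_z <- function(fit_below, fit_above,
                        covariates = c("age", "bmi")) {
  rows <- lapply(covariates, function(v) {
    if (!v %in% rownames(fit_below$coefficients) ||
        !v %in% rownames(fit_above$coefficients))
      stop("covariate '", v, "' absent from one of the fits")
    cb <- fit_below$coefficients[v, ]
    ca <- fit_above$coefficients[v, ]
    z <- (cb$estimate - ca$estimate) / sqrt(cb$se^2 + ca$se^2)
    data.frame(covariate = v,
               coef_below = cb$estimate, se_below = cb$se,
               coef_above = ca$estimate, se_above = ca$se,
               z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interaction test across a PSA split
#'
#' Fits the multiplicative model separately in the strata with PSA below
#' and at-or-above `split_at` and tests, per covariate, whether the
#' coefficients differ, using the combined-standard-error Z statistic of
#' [coef_diff_z()]. This probes whether associations estimated among
#' unbiopsied (low-PSA) men differ from those among biopsied men.
#' `case_status` is included in a stratum's fit only when both cases and
#' controls are present there (below a 3.0 ng/ml referral cutoff a
#' diagnosed-case stratum is typically empty, making the indicator
#' degenerate).
#'
#' @param cohort Cohort `data.frame`.
#' @param split_at PSA split point in ng/ml; the upper stratum is
#'   `psa >= split_at`.
#' @param covariates Covariates to fit and compare.
#' @return `data.frame` as in [coef_diff_z()] plus stratum sizes in
#'   attributes `n_below` / `n_above`.
#' @export
interaction_test <- function(cohort, split_at = 3.0,
                             covariates = c("age", "bmi")) {
  below <- cohort[cohort$psa < split_at, , drop = FALSE]
  above <- cohort[cohort$psa >= split_at, , drop = FALSE]
  p <- length(covariates) + 2L
  if (nrow(below) <= p || nrow(above) <= p)
    stop("a stratum is too small to fit the model (below: ", nrow(below),
         ", above: ", nrow(above), " records)")
  fit_stratum <- function(d)
    fit_log_psa(d, covariates,
                include_case_status = length(unique(d$case_status)) == 2L)
  res <- coef_diff_z(fit_stratum(below), fit_stratum(above), covariates)
  attr(res, "n_below") <- nrow(below)
  attr(res, "n_above") <- nrow(above)
  res
}
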