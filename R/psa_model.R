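#' Fit the multiplicative (log-linear) PSA model
#'
#' Ordinary least squares of \eqn{\ln(\mathrm{PSA})} on age and/or BMI, with
#' case-control status optionally included as a covariate so that
#' associations of age and BMI with cancer itself do not leak into the
#' age/BMI coefficients. Standard errors are the usual homoskedastic OLS
#' ones and 95% confidence intervals come from the t distribution on
#' \eqn{n - p} degrees of freedom.
#'
#' Coefficients are stored per unit (per year of age, per kg/m2 of BMI);
#' use [percent_change_per_5()] for the conventional per-5-unit percentage
#' presentation. The fitted cohort's mean age and BMI are recorded as the
#' default reference point for [adjust_psa()].
#'
#' @param cohort Cohort `data.frame` with positive `psa` and the requested
#'   covariate columns complete.
#' @param covariates Character subset of `c("age", "bmi")`.
#' @param include_case_status Include the `case_status` indicator?
#' @return A `psa_fit` object: `coefficients` table (term, estimate, se,
#'   ci_low, ci_high), `n`, `covariates`, `include_case_status`, `ref_age`,
#'   `ref_bmi`, `sigma`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_controls = 400, n_cases = 100,
#'                                      seed = 3))
#' fit <- fit_log_psa(coh)
#' percent_change_per_5(fit$coefficients["age", "estimate"])
#' @export
fit_log_psa <- function(cohort, covariates = c("age", "bmi"),
                        include_case_status = TRUE) {
  if (length(covariates) == 0 || !all(covariates %in% c("age", "bmi")))
    stop("covariates must be a non-empty subset of c(\"age\", \"bmi\")")
  need <- c("psa", covariates, if (include_case_status) "case_status")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(cohort$psa) | cohort$psa <= 0)
  if (length(bad) > 0) {
    lab <- if ("id" %in% names(cohort)) cohort$id[bad] else bad
    stop("non-positive or missing psa in record(s): ",
         paste(utils::head(lab, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }
  for (v in need)
    if (anyNA(cohort[[v]])) stop("missing values in column '", v, "'")
  terms <- c(covariates, if (include_case_status) "case_status")
  p <- length(terms) + 1L
  if (nrow(cohort) < p + 1L)
    stop("fewer records (", nrow(cohort), ") than model parameters require")
  fml <- stats::as.formula(paste("log(psa) ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = cohort)
  # zero-noise cohorts fit exactly; the "essentially perfect fit" warning
  # is expected there, not a defect
  quiet_perfect <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  smry <- quiet_perfect(summary(fit))
  sm <- smry$coefficients
  ci <- quiet_perfect(stats::confint(fit, level = 0.95))
  tab <- data.frame(term = rownames(sm),
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    stringsAsFactors = FALSE)
  rownames(tab) <- tab$term
  structure(list(coefficients = tab, n = nrow(cohort),
                 covariates = covariates,
                 include_case_status = include_case_status,
                 ref_age = if ("age" %in% names(cohort)) mean(cohort$age) else NA_real_,
                 ref_bmi = if ("bmi" %in% names(cohort)) mean(cohort$bmi) else NA_real_,
                 sigma = smry$sigma),
            class = "psa_fit")
}

#' @export
print.psa_fit <- function(x, ...) {
  cat("Log-linear PSA model (n =", x$n, ")\n")
  tab <- x$coefficients
  tab$pct_per_5 <- ifelse(tab$term %in% c("age", "bmi"),
                          percent_change_per_5(tab$estimate), NA)
  print(tab, digits = 4, row.names = FALSE)
  cat(sprintf("reference age %.2f y, BMI %.2f kg/m2; residual SD %.3f\n",
              x$ref_age, x$ref_bmi, x$sigma))
  invisible(x)
}

#' Convert a per-unit ln(PSA) slope to a per-5-unit percentage change
#'
#' Returns \eqn{100\,(e^{5\beta} - 1)}: the percentage by which PSA is
#' multiplied over a 5-year (or 5 kg/m2) increase in the covariate.
#'
#' @param coef_per_unit Slope on the ln(PSA) scale per unit of covariate.
#' @return Percentage change (vectorised).
#' @examples
#' percent_change_per_5(0.126 / 5)   # 13.43
#' @export
percent_change_per_5 <- function(coef_per_unit) {
  if (any(!is.finite(coef_per_unit))) stop("coefficient must be finite")
  100 * (exp(5 * coef_per_unit) - 1)
}

#' Parameters of the PSA adjustment equation
#'
#' Bundles the per-unit coefficients and reference (mean) age/BMI used by
#' [adjust_psa()]. `mode` selects which effects are removed; the unused
#' coefficient is treated as zero.
#'
#' @param age_coef,bmi_coef Per-unit ln(PSA) slopes.
#' @param ref_age,ref_bmi Reference age (years) and BMI (kg/m2) — typically
#'   the fitted cohort means.
#' @param mode One of `"age"`, `"bmi"`, `"age_bmi"`.
#' @return An `adjustment_params` object.
#' @export
adjustment_params <- function(age_coef = 0, bmi_coef = 0,
                              ref_age = 0, ref_bmi = 0,
                              mode = c("age_bmi", "age", "bmi")) {
  mode <- match.arg(mode)
  if (mode == "age") bmi_coef <- 0
  if (mode == "bmi") age_coef <- 0
  structure(list(age_coef = age_coef, bmi_coef = bmi_coef,
                 ref_age = ref_age, ref_bmi = ref_bmi, mode = mode),
            class = "adjustment_params")
}

#' Extract adjustment parameters from a fitted PSA model
#'
#' @param fit A [fit_log_psa()] result containing the coefficients the
#'   chosen `mode` needs.
#' @param mode Which effects to remove: `"age"`, `"bmi"` or `"age_bmi"`.
#' @return An [adjustment_params()] object with the fit's sample means as
#'   the reference point.
#' @export
as_adjustment_params <- function(fit, mode = c("age_bmi", "age", "bmi")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "psa_fit")) stop("fit must be a psa_fit object")
  getco <- function(term) {
    if (!term %in% rownames(fit$coefficients))
      stop("fit has no '", term, "' coefficient needed for mode ", mode)
    fit$coefficients[term, "estimate"]
  }
  adjustment_params(
    age_coef = if (mode != "bmi") getco("age") else 0,
    bmi_coef = if (mode != "age") getco("bmi") else 0,
    ref_age = fit$ref_age, ref_bmi = fit$ref_bmi, mode = mode)
}

#' Adjust an observed PSA to reference age and BMI
#'
#' Applies the multiplicative adjustment
#' \deqn{\mathrm{PSA}_{adj} = \mathrm{PSA} / e^{a\,\beta_{age} + b\,\beta_{bmi}}}
#' where \eqn{a} and \eqn{b} are the differences between the man's age/BMI
#' and the reference values. The result is the PSA the man would be expected
#' to have at reference age and BMI: it is strictly positive and
#' order-preserving in the observed PSA at fixed age and BMI.
#'
#' @param psa Observed PSA in ng/ml (> 0, vectorised).
#' @param age,bmi Subject age (years) and BMI (kg/m2).
#' @param params An [adjustment_params()] object.
#' @return Adjusted PSA in ng/ml.
#' @examples
#' p <- adjustment_params(age_coef = 0.126 / 5, ref_age = 61.7,
#'                        mode = "age")
#' adjust_psa(4.0, age = 66.7, bmi = 27.2, params = p)  # 4 / exp(0.126)
#' @export
adjust_psa <- function(psa, age, bmi, params) {
  if (!inherits(params, "adjustment_params"))
    stop("params must be built with adjustment_params()")
  if (any(!is.finite(psa) | psa <= 0))
    stop("psa must be strictly positive")
  a <- age - params$ref_age
  b <- bmi - params$ref_bmi
  psa / exp(a * params$age_coef + b * params$bmi_coef)
}

#' Append adjusted-PSA columns to a cohort
#'
#' Adds `psa_adj_age`, `psa_adj_bmi` and `psa_adj_age_bmi` columns. The two
#' single-covariate adjustments use coefficients from the corresponding
#' single-covariate regression (age alone, BMI alone) and the joint
#' adjustment uses the multivariable fit, mirroring a derivation of the
#' effects "separately and together"; all regressions share the
#' `include_case_status` choice.
#'
#' @param cohort Cohort `data.frame`.
#' @param include_case_status Passed to [fit_log_psa()].
#' @param fits Optional pre-computed list with elements `age`, `bmi`,
#'   `age_bmi` (each a `psa_fit`, e.g. from training data in
#'   cross-validation); when supplied no fitting happens here.
#' @return The cohort with the three extra columns, plus the fits used in
#'   attribute `"fits"`.
#' @export
add_adjusted_psa <- function(cohort, include_case_status = TRUE,
                             fits = NULL) {
  if (is.null(fits)) {
    fits <- list(
      age = fit_log_psa(cohort, "age", include_case_status),
      bmi = fit_log_psa(cohort, "bmi", include_case_status),
      age_bmi = fit_log_psa(cohort, c("age", "bmi"), include_case_status))
  }
  cohort$psa_adj_age <- adjust_psa(cohort$psa, cohort$age, cohort$bmi,
                                   as_adjustment_params(fits$age, "age"))
  cohort$psa_adj_bmi <- adjust_psa(cohort$psa, cohort$age, cohort$bmi,
                                   as_adjustment_params(fits$bmi, "bmi"))
  cohort$psa_adj_age_bmi <-
    adjust_psa(cohort$psa, cohort$age, cohort$bmi,
               as_adjustment_params(fits$age_bmi, "age_bmi"))
  attr(cohort, "fits") <- fits
  cohort
}
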