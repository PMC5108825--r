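#!/usr/bin/env Rscript
# Stage 2: fit the multiplicative log-PSA models and append adjusted PSAs.
#
# Fits univariable (age alone, BMI alone) and multivariable (age + BMI)
# regressions of ln(PSA), each with case-control status as a covariate,
# plus a controls-only refit as a sensitivity analysis, and writes the
# coefficient tables and the cohort with psa_adj_* columns.

library(psaadjust)
cohort <- read_cohort("results/cohort.csv")

adj <- add_adjusted_psa(cohort)
fits <- attr(adj, "fits")
write_fit(fits$age, "results/fit_univariable_age.csv")
write_fit(fits$bmi, "results/fit_univariable_bmi.csv")
write_fit(fits$age_bmi, "results/fit_multivariable.csv")
write_cohort(adj, "results/cohort_adjusted.csv")

report <- function(label, fit) {
  for (v in intersect(c("age", "bmi"), rownames(fit$coefficients))) {
    co <- fit$coefficients[v, ]
    cat(sprintf(
      "%s %s: %+.2f%% per 5 units (per-5 coef %.3f, 95%% CI %.3f to %.3f)\n",
      label, v, percent_change_per_5(co$estimate), 5 * co$estimate,
      5 * co$ci_low, 5 * co$ci_high))
  }
}
report("univariable", fits$age)
report("univariable", fits$bmi)
report("multivariable", fits$age_bmi)

controls <- cohort[cohort$case_status == 0, ]
fit_ctrl <- fit_log_psa(controls, include_case_status = FALSE)
write_fit(fit_ctrl, "results/fit_controls_only.csv")
report("controls-only", fit_ctrl)
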