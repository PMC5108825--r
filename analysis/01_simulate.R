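#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Draws a case-control cohort at the study calibration (9,457 controls,
# 1,836 cases, ages 50-69, BMI ~ N(27.2, 3.73^2), control median PSA
# 1.0 ng/ml, case median 5.0 ng/ml conditioned on the 3.0 ng/ml biopsy
# referral), applies the inclusion filters, and writes the cohort and the
# exclusion tally under results/.

library(psaadjust)
seed <- 20260926L
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
filt <- apply_inclusion_filters(cohort, max_control_psa = cfg$control_max_psa)
cohort <- filt$cohort

write_cohort(cohort, "results/cohort.csv")
write.csv(filt$exclusions, "results/exclusions.csv", row.names = FALSE)

ctrl <- cohort$psa[cohort$case_status == 0]
cas <- cohort$psa[cohort$case_status == 1]
cat(sprintf("cohort: %d controls, %d cases\n", length(ctrl), length(cas)))
cat(sprintf("control PSA median (IQR): %.2f (%.2f-%.2f) ng/ml\n",
            median(ctrl), quantile(ctrl, 0.25), quantile(ctrl, 0.75)))
cat(sprintf("case PSA median (IQR): %.2f (%.2f-%.2f) ng/ml\n",
            median(cas), quantile(cas, 0.25), quantile(cas, 0.75)))
cat(sprintf("mean age %.1f y (SD %.2f); mean BMI %.1f kg/m2 (SD %.2f)\n",
            mean(cohort$age), sd(cohort$age), mean(cohort$bmi),
            sd(cohort$bmi)))
cat("exclusions by rule:\n")
print(filt$exclusions, row.names = FALSE)
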