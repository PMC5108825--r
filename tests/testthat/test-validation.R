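test_that("fold assignment partitions each stratum almost evenly", {
  status <- c(rep(1, 83), rep(0, 417))
  fold <- make_folds(status, k = 10, seed = 91)
  expect_equal(length(fold), 500)
  expect_true(all(fold %in% 1:10))
  for (s in 0:1) {
    sizes <- tabulate(fold[status == s], nbins = 10)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_identical(fold, make_folds(status, k = 10, seed = 91))
  expect_false(identical(fold, make_folds(status, k = 10, seed = 92)))
})

test_that("cross-validation is exactly stable on deterministic cohorts", {
  coh <- generate_cohort(cohort_config(
    n_controls = 400, n_cases = 100, beta_age = 0, beta_bmi = 0,
    control_log_sd = 0, case_log_sd = 0, seed = 93))
  cv <- tenfold_cv(coh, rules = list(fixed_rule(3), fixed_rule(4),
                                     nice_rule()), seed = 94)
  expect_true(all(cv$summary$sd_sensitivity == 0))
  expect_true(all(cv$summary$sd_specificity == 0))
  expect_true(all(cv$summary$mean_sensitivity == 1))
  expect_true(all(cv$summary$mean_specificity == 1))
})

test_that("cross-validation is reproducible under its seed", {
  coh <- generate_cohort(cohort_config(n_controls = 300, n_cases = 80,
                                       seed = 95))
  cv1 <- tenfold_cv(coh, models = c("observed", "age_bmi"), seed = 96)
  cv2 <- tenfold_cv(coh, models = c("observed", "age_bmi"), seed = 96)
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$assignment, cv2$assignment)
})

test_that("fold-averaged accuracy tracks the full-sample analysis", {
  coh <- generate_cohort(cohort_config(seed = 97))  # study-sized default
  rules <- list(fixed_rule(3), fixed_rule(4), nice_rule())
  cv <- tenfold_cv(coh, rules = rules, seed = 98)
  full <- evaluate_thresholds(
    add_adjusted_psa(coh),
    c(observed = "psa", age = "psa_adj_age", bmi = "psa_adj_bmi",
      age_bmi = "psa_adj_age_bmi"), rules)
  merged <- merge(cv$summary, full, by = c("model", "rule"))
  expect_equal(nrow(merged), nrow(cv$summary))
  expect_true(all(abs(merged$mean_sensitivity - merged$sensitivity) < 0.02))
  expect_true(all(abs(merged$mean_specificity - merged$specificity) < 0.02))
})

test_that("a fold with an empty margin is reported by name", {
  coh <- generate_cohort(cohort_config(n_controls = 100, n_cases = 5,
                                       seed = 99))
  expect_error(tenfold_cv(coh, models = "observed", seed = 100),
               "fold .* no cases")
})

test_that("the coefficient-difference Z is zero on identical strata and
           antisymmetric under swapping", {
  coh <- generate_cohort(cohort_config(n_controls = 300, n_cases = 80,
                                       seed = 111))
  fit <- fit_log_psa(coh)
  same <- coef_diff_z(fit, fit)
  expect_equal(same$z, c(0, 0))
  expect_equal(same$p, c(1, 1))
  other <- fit_log_psa(generate_cohort(
    cohort_config(n_controls = 300, n_cases = 80, seed = 112)))
  ab <- coef_diff_z(fit, other)
  ba <- coef_diff_z(other, fit)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("interaction test errors on a degenerate stratum", {
  coh <- generate_cohort(cohort_config(n_controls = 200, n_cases = 50,
                                       seed = 113))
  expect_error(interaction_test(coh, split_at = 1e6), "too small")
})

# Simulation checks of the interaction Z-test's calibration. Strata are
# separated by construction (controls near 1 ng/ml, cases near 8 ng/ml,
# small ln-scale SD) so that the PSA split at 3.0 is effectively exogenous
# and each stratum is a clean linear model.
interaction_sim_config <- function(seed, case_beta_age = 0.126 / 5) {
  list(
    ctrl = cohort_config(n_controls = 250, n_cases = 0,
                         control_log_sd = 0.15, control_max_psa = Inf,
                         seed = seed),
    case = cohort_config(n_controls = 0, n_cases = 250,
                         case_log_median = log(8), case_log_sd = 0.15,
                         beta_age = case_beta_age, case_min_psa = 0,
                         case_max_psa = Inf, seed = seed + 500000L))
}

test_that("the interaction test holds its nominal type-I error", {
  reject <- matrix(FALSE, 500, 2)
  for (i in 1:500) {
    cfgs <- interaction_sim_config(120000L + i)
    coh <- rbind(generate_cohort(cfgs$ctrl), generate_cohort(cfgs$case))
    res <- interaction_test(coh, split_at = 3.0)
    reject[i, ] <- res$p < 0.05
  }
  bounds <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  for (j in 1:2) {
    rate <- mean(reject[, j])
    expect_gte(rate, bounds[1])
    expect_lte(rate, bounds[2])
  }
})

test_that("the interaction test detects a 3-combined-SE slope difference", {
  # expected per-stratum SE of the age slope from the homoskedastic formula
  pilot <- generate_cohort(interaction_sim_config(130000L)$ctrl)
  se1 <- 0.15 / sqrt(250 * stats::var(pilot$age))
  delta <- 3 * sqrt(2) * se1
  reject <- logical(300)
  for (i in 1:300) {
    cfgs <- interaction_sim_config(131000L + i,
                                   case_beta_age = 0.126 / 5 + delta)
    coh <- rbind(generate_cohort(cfgs$ctrl), generate_cohort(cfgs$case))
    reject[i] <- interaction_test(coh, split_at = 3.0)$p[1] < 0.05
  }
  expect_gt(mean(reject), 0.8)
})
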