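test_that("the verification-example cohort cross-tabulates exactly", {
  counts <- classify(box2_cohort(), "psa", fixed_rule(3.0))
  expect_equal(counts$tp, 1900)
  expect_equal(counts$fn, 0)
  expect_equal(counts$fp, 1100)
  expect_equal(counts$tn, 7000)
})

test_that("a score exactly at the cutoff counts as positive", {
  coh <- data.frame(id = as.character(1:10), age = 60, bmi = 27,
                    psa = c(4.0, 3.9, 4.1, 5, 2, 4.0, 3.99, 6, 1, 4.01),
                    case_status = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                    stringsAsFactors = FALSE)
  counts <- classify(coh, "psa", fixed_rule(4.0))
  # hand tally with >= at 4.0: cases 4.0/4.1/5 positive, 3.9/2 negative;
  # controls 4.0/6/4.01 positive, 3.99/1 negative
  expect_equal(counts$tp, 3)
  expect_equal(counts$fn, 2)
  expect_equal(counts$fp, 3)
  expect_equal(counts$tn, 2)
})

test_that("all scores below every cutoff give zero positives", {
  coh <- data.frame(id = as.character(1:6), age = rep(c(55, 65, 72), 2),
                    bmi = 27, psa = 0.5, case_status = rep(c(1, 0), 3),
                    stringsAsFactors = FALSE)
  counts <- classify(coh, "psa", nice_rule())
  expect_equal(counts$tp + counts$fp, 0)
})

test_that("sensitivity and specificity follow the margin definitions", {
  ss <- sens_spec(confusion_counts(tp = 2000, fn = 500, tn = 6500,
                                   fp = 1000))
  expect_equal(ss$sensitivity, 0.8)
  expect_equal(ss$specificity, 6500 / 7500, tolerance = 1e-12)
  ss <- sens_spec(confusion_counts(tp = 1900, fn = 0, tn = 7000, fp = 1100))
  expect_equal(ss$sensitivity, 1)
  expect_equal(round(ss$specificity, 4), 0.8642)
  ss <- sens_spec(confusion_counts(tp = 50, fn = 0, tn = 70, fp = 0))
  expect_equal(c(ss$sensitivity, ss$specificity), c(1, 1))
  expect_error(sens_spec(confusion_counts(tp = 0, fn = 0, tn = 5, fp = 5)),
               "no cases")
  expect_error(sens_spec(confusion_counts(tp = 5, fn = 5, tn = 0, fp = 0)),
               "no controls")
})

test_that("the NICE age bands map ages to their cutoffs", {
  expect_equal(nice_threshold(c(55, 65, 72)), c(3.0, 4.0, 5.0))
  expect_equal(nice_threshold(59.9), 3.0)  # completed-years membership
  expect_equal(nice_threshold(c(50, 60, 70)), c(3.0, 4.0, 5.0))
  expect_error(nice_threshold(49), "outside the guideline")
  coh <- data.frame(id = "young", age = 45, bmi = 27, psa = 4,
                    case_status = 1, stringsAsFactors = FALSE)
  expect_error(classify(coh, "psa", nice_rule()), "young")
})

test_that("age-banded rules reject overlapping or malformed bands", {
  expect_error(age_banded_rule(data.frame(age_low = c(50, 55),
                                          age_high = c(59, 69),
                                          cutoff = c(3, 4))), "overlap")
  expect_error(fixed_rule(-1), "> 0")
})

test_that("matched-specificity search picks the smallest adequate threshold", {
  coh <- data.frame(id = as.character(1:6), age = 60, bmi = 27,
                    psa = c(4, 5, 1, 2, 3, 4),
                    case_status = c(1, 1, 0, 0, 0, 0),
                    stringsAsFactors = FALSE)
  res <- matched_specificity_sensitivity(coh, "psa", 0.75)
  expect_equal(res$threshold, 4)
  expect_equal(res$achieved_specificity, 0.75)
  expect_equal(res$sensitivity, 1)
  # target near 1: threshold must clear the largest control score
  res <- matched_specificity_sensitivity(coh, "psa", 0.999)
  expect_gt(res$threshold, 4)
  expect_equal(res$achieved_specificity, 1)
  expect_equal(res$sensitivity, 0.5)
})

test_that("matched-specificity search agrees with an exhaustive scan", {
  for (seed in c(13, 14)) {
    coh <- generate_cohort(cohort_config(n_controls = 400, n_cases = 100,
                                         seed = seed))
    for (target in c(0.8, 0.932, 0.99)) {
      res <- matched_specificity_sensitivity(coh, "psa", target)
      cand <- c(sort(unique(coh$psa)), Inf)
      spec <- vapply(cand,
                     function(t) mean(coh$psa[coh$case_status == 0] < t),
                     numeric(1))
      best <- min(cand[spec >= target])
      expect_equal(res$threshold, best)
      expect_equal(res$sensitivity,
                   mean(coh$psa[coh$case_status == 1] >= best))
      expect_gte(res$achieved_specificity, target)
    }
  }
})

test_that("sensitivity falls and specificity rises along the cutoff path", {
  coh <- generate_cohort(cohort_config(n_controls = 500, n_cases = 150,
                                       seed = 15))
  cuts <- sort(unique(coh$psa))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    ss <- sens_spec(classify(coh, "psa", fixed_rule(cuts[i])))
    sens[i] <- ss$sensitivity; spec[i] <- ss$specificity
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("classification is order-invariant and scales under duplication", {
  coh <- generate_cohort(cohort_config(n_controls = 80, n_cases = 40,
                                       seed = 16))
  a <- classify(coh, "psa", nice_rule())
  b <- classify(coh[rev(seq_len(nrow(coh))), ], "psa", nice_rule())
  expect_identical(unclass(a), unclass(b))
  dup <- classify(rbind(coh, coh, coh), "psa", nice_rule())
  expect_equal(unlist(unclass(dup)), 3 * unlist(unclass(a)))
})

test_that("McNemar p-values match their closed forms and stats oracles", {
  expect_equal(mcnemar_p(7, 7)$p, 1)
  expect_equal(mcnemar_p(10, 0)$p, 0.001953125, tolerance = 1e-12)
  expect_warning(res <- mcnemar_p(0, 0), "no discordant")
  expect_equal(res$p, 1)
  # exact path against binom.test
  for (bc in list(c(3, 9), c(5, 12), c(1, 20))) {
    expect_equal(mcnemar_p(bc[1], bc[2], "exact")$p,
                 stats::binom.test(bc[1], sum(bc), 0.5)$p.value,
                 tolerance = 1e-12)
  }
  # corrected chi-square path against stats::mcnemar.test
  for (bc in list(c(20, 40), c(15, 15), c(8, 30))) {
    m <- matrix(c(5, bc[2], bc[1], 5), 2)
    expect_equal(mcnemar_p(bc[1], bc[2], "chisq")$p,
                 stats::mcnemar.test(m, correct = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # auto switches at b + c = 25
  expect_equal(mcnemar_p(12, 12)$method, "exact")
  expect_equal(mcnemar_p(12, 13)$method, "chisq")
})

test_that("classifier comparison counts correctness discordance", {
  # cases at 3.5 are caught by a fixed 3.0 rule but missed by NICE for
  # men in their sixties (cutoff 4.0)
  coh <- data.frame(id = as.character(1:8), age = c(rep(65, 4), rep(55, 4)),
                    bmi = 27,
                    psa = c(3.5, 3.5, 1, 5, 2, 2, 6, 3.2),
                    case_status = c(1, 1, 0, 1, 0, 0, 1, 0),
                    stringsAsFactors = FALSE)
  res <- mcnemar_compare(coh, "psa", fixed_rule(3.0), "psa", nice_rule())
  # hand tally: only the two 65-year-old cases at 3.5 are discordant
  # (correct under the fixed rule, missed under the NICE 4.0 band); every
  # other subject is classified identically by both rules
  expect_equal(res$b, 2)
  expect_equal(res$c, 0)
  expect_equal(res$p_value, min(1, 2 * 0.5^2))
})
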