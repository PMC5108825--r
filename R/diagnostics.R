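#' Threshold rules for PSA positivity
#'
#' A threshold rule maps a subject to the PSA cutoff above which (inclusive)
#' the test is called positive. `fixed_rule()` applies one cutoff to
#' everyone; `age_banded_rule()` applies a cutoff per age band, with band
#' membership by completed years (`floor(age)`, since guideline bands are
#' stated in whole years); `nice_rule()` is the NICE age-banded rule:
#' 50-59 years: 3.0 ng/ml, 60-69: 4.0, 70+: 5.0.
#'
#' @param cutoff Positive PSA cutoff in ng/ml.
#' @param bands `data.frame` with columns `age_low`, `age_high`, `cutoff`;
#'   bands must be non-overlapping in completed years.
#' @return A `threshold_rule` object.
#' @examples
#' threshold_for(nice_rule(), c(55, 65, 72))
#' @export
fixed_rule <- function(cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(kind = "fixed", cutoff = cutoff,
                 label = sprintf("fixed %.1f ng/ml", cutoff)),
            class = "threshold_rule")
}

#' @rdname fixed_rule
#' @export
age_banded_rule <- function(bands) {
  need <- c("age_low", "age_high", "cutoff")
  if (!is.data.frame(bands) || !all(need %in% names(bands)))
    stop("bands needs columns age_low, age_high, cutoff")
  if (any(bands$cutoff <= 0)) stop("cutoffs must be > 0")
  bands <- bands[order(bands$age_low), , drop = FALSE]
  if (any(bands$age_low > bands$age_high)) stop("bands must be ordered pairs")
  if (nrow(bands) > 1 &&
      any(bands$age_low[-1] <= bands$age_high[-nrow(bands)]))
    stop("bands overlap")
  structure(list(kind = "age_banded", bands = bands, label = "age-banded"),
            class = "threshold_rule")
}

#' @rdname fixed_rule
#' @export
nice_rule <- function() {
  r <- age_banded_rule(data.frame(age_low = c(50, 60, 70),
                                  age_high = c(59, 69, Inf),
                                  cutoff = c(3.0, 4.0, 5.0)))
  r$label <- "NICE age-banded"
  r
}

#' Cutoff applicable to each subject under a rule
#'
#' @param rule A `threshold_rule`.
#' @param age Ages in years (ignored for fixed rules); fractional ages
#'   belong to the band of their completed year.
#' @param id Optional subject labels used in error messages.
#' @return Numeric vector of cutoffs (ng/ml).
#' @export
threshold_for <- function(rule, age, id = NULL) {
  if (!inherits(rule, "threshold_rule")) stop("not a threshold_rule")
  if (rule$kind == "fixed") return(rep(rule$cutoff, length(age)))
  yr <- floor(age)
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(rule$bands)))
    idx[yr >= rule$bands$age_low[i] & yr <= rule$bands$age_high[i]] <- i
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    lab <- if (!is.null(id)) id[bad] else bad
    stop("age outside all bands for subject(s): ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  rule$bands$cutoff[idx]
}

#' NICE age-specific PSA cutoff
#'
#' @param age Age in years (>= 50; the guideline table starts at 50).
#' @return Cutoff in ng/ml: 3.0 for ages 50-59, 4.0 for 60-69, 5.0 for 70+.
#' @examples
#' nice_threshold(c(55, 65, 72))
#' @export
nice_threshold <- function(age) {
  if (any(age < 50)) stop("age below 50 is outside the guideline table")
  threshold_for(nice_rule(), age)
}

#' Cross-tabulate test positivity against case status
#'
#' A subject is test-positive iff the score is at or above (`>=`) the
#' applicable cutoff. Counts are tallied against `case_status`.
#'
#' @param cohort Cohort `data.frame` with `case_status` and the score
#'   column; age-banded rules additionally need `age`.
#' @param score_column Name of the score column (e.g. `"psa"`,
#'   `"psa_adj_age_bmi"`).
#' @param rule A `threshold_rule`.
#' @return A `confusion_counts` object with `tp`, `fp`, `tn`, `fn`.
#' @export
classify <- function(cohort, score_column = "psa", rule = fixed_rule(3.0)) {
  if (!score_column %in% names(cohort))
    stop("score column '", score_column, "' not found")
  score <- cohort[[score_column]]
  if (any(!is.finite(score) | score <= 0))
    stop("scores in '", score_column, "' must be positive")
  cut <- threshold_for(rule, cohort$age, id = cohort$id)
  pos <- score >= cut
  case <- cohort$case_status == 1
  confusion_counts(tp = sum(pos & case), fp = sum(pos & !case),
                   tn = sum(!pos & !case), fn = sum(!pos & case))
}

#' @rdname classify
#' @param tp,fp,tn,fn Non-negative counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || anyNA(v)) stop("counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Sensitivity and specificity of a confusion table
#'
#' Sensitivity is the proportion of cases at or above the cutoff,
#' tp / (tp + fn); specificity the proportion of controls below it,
#' tn / (tn + fp).
#'
#' @param counts A [confusion_counts()] object.
#' @return A list with `sensitivity` and `specificity`.
#' @examples
#' sens_spec(confusion_counts(tp = 2000, fp = 1000, tn = 6500, fn = 500))
#' @export
sens_spec <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    stop("counts must be a confusion_counts object")
  if (counts$tp + counts$fn == 0)
    stop("no cases: sensitivity denominator is empty")
  if (counts$tn + counts$fp == 0)
    stop("no controls: specificity denominator is empty")
  list(sensitivity = counts$tp / (counts$tp + counts$fn),
       specificity = counts$tn / (counts$tn + counts$fp))
}

#' Evaluate several score columns under several threshold rules
#'
#' Convenience wrapper building a model-by-rule accuracy table (one row per
#' combination) from [classify()] and [sens_spec()].
#'
#' @param cohort Cohort `data.frame` (with adjusted columns as needed).
#' @param score_columns Named character vector: names are display labels,
#'   values are column names.
#' @param rules List of `threshold_rule`s.
#' @return `data.frame` with model, rule, sensitivity, specificity.
#' @export
evaluate_thresholds <- function(cohort,
                                score_columns = c(observed = "psa"),
                                rules = list(fixed_rule(3), fixed_rule(4))) {
  labels <- names(score_columns)
  if (is.null(labels)) labels <- score_columns
  rows <- list()
  for (i in seq_along(score_columns)) {
    for (r in rules) {
      ss <- sens_spec(classify(cohort, score_columns[[i]], r))
      rows[[length(rows) + 1L]] <-
        data.frame(model = labels[i], rule = r$label,
                   sensitivity = ss$sensitivity,
                   specificity = ss$specificity,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity at a matched specificity
#'
#' Finds the operating point of a score that matches a target specificity:
#' candidate thresholds are the distinct score values plus `Inf`, and the
#' smallest threshold whose specificity is at least the target is returned
#' (which maximises sensitivity subject to the specificity constraint).
#'
#' @param cohort Cohort `data.frame` with positive scores.
#' @param score_column Score column name.
#' @param target_specificity Target in (0, 1).
#' @return List with `threshold`, `achieved_specificity`, `sensitivity`.
#' @export
matched_specificity_sensitivity <- function(cohort, score_column,
                                            target_specificity) {
  if (!is.finite(target_specificity) ||
      target_specificity <= 0 || target_specificity >= 1)
    stop("target_specificity must lie strictly within (0, 1)")
  score <- cohort[[score_column]]
  if (any(!is.finite(score) | score <= 0)) stop("scores must be positive")
  case <- cohort$case_status == 1
  ctrl_scores <- score[!case]
  case_scores <- score[case]
  if (length(ctrl_scores) == 0 || length(case_scores) == 0)
    stop("both cases and controls are required")
  cand <- c(sort(unique(score)), Inf)
  for (t in cand) {
    spec <- mean(ctrl_scores < t)
    if (spec >= target_specificity)
      return(list(threshold = t, achieved_specificity = spec,
                  sensitivity = mean(case_scores >= t)))
  }
  stop("unreachable target specificity")  # cannot happen for target < 1
}

#' Compare two threshold classifiers with McNemar's test
#'
#' Each subject is classified correctly by a rule iff the subject is a case
#' at or above its cutoff, or a control below it. Discordance is defined on
#' correctness (not raw positivity) so that rules with different cutoffs --
#' e.g. an adjusted-PSA threshold against the NICE age bands -- remain
#' comparable. `b` counts subjects correct under A only, `c` correct under
#' B only. The default `"auto"` method uses the exact two-sided binomial
#' test when `b + c < 25` and the continuity-corrected chi-square otherwise.
#'
#' @param cohort Cohort `data.frame`.
#' @param score_a,score_b Score column names for classifiers A and B.
#' @param rule_a,rule_b `threshold_rule`s for A and B.
#' @param method `"auto"`, `"exact"` or `"chisq"`.
#' @return List with `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_compare <- function(cohort, score_a, rule_a, score_b, rule_b,
                            method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  correct <- function(column, rule) {
    cut <- threshold_for(rule, cohort$age, id = cohort$id)
    pos <- cohort[[column]] >= cut
    (cohort$case_status == 1) == pos
  }
  ca <- correct(score_a, rule_a)
  cb <- correct(score_b, rule_b)
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  res <- mcnemar_p(b, c_, method)
  list(b = b, c = c_, p_value = res$p, method = res$method)
}

# p-value arithmetic shared by mcnemar_compare; exposed for direct use on
# discordant counts.
#' McNemar p-value from discordant counts
#'
#' @param b,c Discordant counts (correct under one classifier only).
#' @param method See [mcnemar_compare()].
#' @return List with `p` and the `method` actually used.
#' @export
mcnemar_p <- function(b, c, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  n <- b + c
  if (n == 0) {
    warning("no discordant pairs; p = 1")
    return(list(p = 1, method = "none"))
  }
  if (method == "auto") method <- if (n < 25) "exact" else "chisq"
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  } else {
    # continuity correction only when the counts differ (as in Edwards'
    # corrected statistic; a zero difference stays a zero statistic)
    stat <- if (b == c) 0 else (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p = p, method = method)
}
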