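---
title: "Age- and BMI-adjusted PSA: models, diagnostics and verification bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age- and BMI-adjusted PSA: models, diagnostics and verification bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psaadjust)
```

## The problem

Prostate-specific antigen (PSA) is the standard serum biomarker used to
decide which men are referred for prostate biopsy. PSA is not influenced
by cancer alone: it rises with age (the ageing prostate contains more
PSA-producing tissue and leaks more of it into serum) and falls with body
mass index (plausibly through haemodilution in a larger plasma volume).
UK practice already uses age-specific referral cutoffs — the NICE bands of
3.0 ng/ml for ages 50–59, 4.0 for 60–69 and 5.0 from 70 — but takes no
account of BMI. `psaadjust` implements the machinery needed to ask whether
a PSA *adjusted* for age and BMI discriminates prostate cancer better than
the observed PSA or the NICE bands: the multiplicative PSA model, the
adjustment equation, threshold diagnostics, a matched-specificity
comparison with McNemar's test, tenfold cross-validation, an interaction
test across the biopsy-referral split, and the arithmetic of verification
(work-up) bias. Because the underlying trial data are not publicly
deposited, the package ships a calibrated synthetic cohort generator so
that every stage is runnable and testable.

## The multiplicative model

A change in age or BMI is assumed to *scale* PSA rather than shift it —
a man with a high PSA should see a larger absolute change than a man with
a low PSA for the same covariate change. On the log scale this is linear:

$$\ln(\mathrm{PSA}_i) = \beta_0 + \beta_{age}\,age_i + \beta_{bmi}\,bmi_i
  + \beta_{ca}\,case_i + \varepsilon_i .$$

`fit_log_psa()` estimates this by ordinary least squares, always including
an intercept and, by default, the case–control indicator: age and BMI are
both associated with prostate cancer itself, and omitting the indicator
would fold those associations into the age and BMI coefficients.
Coefficients are stored per unit (per year, per kg/m²); the conventional
report is the per-5-unit percentage change
$100\,(e^{5\beta}-1)$, computed by `percent_change_per_5()` from the
*unrounded* coefficient (a percentage computed from a rounded coefficient
can disagree in the second decimal). Standard errors are homoskedastic OLS
ones and 95% intervals use the $t$ distribution on $n-p$ degrees of
freedom; no robust variance option is offered because nothing in the
intended use requires one.

The adjusted PSA divides out the estimated age and BMI effects:

$$\mathrm{PSA}_{adj} = \frac{\mathrm{PSA}}
  {e^{\,a\,\beta_{age} + b\,\beta_{bmi}}},$$

where $a$ and $b$ are the differences between the man's age and BMI and
the reference values (by default the fitted cohort's means, overridable
via `adjustment_params()`). The result is interpretable as the PSA the man
would have at reference age and BMI; it is strictly positive, monotone in
the observed PSA, decreasing in age (positive age coefficient) and
increasing in BMI (negative BMI coefficient). `add_adjusted_psa()` appends
three adjusted columns: the single-covariate adjustments take their
coefficient from the corresponding single-covariate regression and the
joint adjustment from the multivariable fit, so each column removes the
effect "as estimated on its own" or "jointly", respectively.

## Threshold diagnostics

`classify()` calls a man test-positive when his score is **at or above**
the applicable cutoff — the age-banded guideline is stated as "≥" — and
band membership uses completed years (`floor(age)`), since guideline
bands are written in whole years. Sensitivity is the proportion of
diagnosed cases at or above the cutoff, specificity the proportion of
controls below it.

An age-banded rule has no single operating point, so comparing it to a
fixed-cutoff model trades sensitivity against specificity. The package
instead matches operating points: `matched_specificity_sensitivity()`
scans the distinct score values (plus $+\infty$) and returns the
*smallest* threshold whose specificity reaches the target — the choice
that maximises sensitivity subject to the specificity constraint; how to
break granularity ties is genuinely open, and this convention is the one
that favours the model being tested. Models are then compared to the
age-banded rule with McNemar's test on **correctness** discordance: a
subject counts as discordant when exactly one rule classifies him
correctly. Discordance on raw positivity would be meaningless across
rules with different cutoffs. The default p-value is the exact two-sided
binomial when the discordant total is below 25 and the
continuity-corrected chi-square otherwise (`mcnemar_p()` exposes both).

## Verification bias

Only men with PSA at or above the referral cutoff are biopsied, so the
study-visible 2×2 table is distorted: with true cells $A, B, C, D$ (cancer
and no-cancer, above and below the cutoff) and $x$ cancers missed at
biopsy, the visible table is $(A-x,\; B+x,\; 0,\; D+C)$. The visible
case-negative cell is structurally zero, so *apparent* sensitivity at the
referral cutoff is identically 1, while true sensitivity is $A/(A+C)$;
apparent specificity $(D+C)/(B+x+D+C)$ stays close to the true $D/(B+D)$,
with absolute error at most $(x+C)/(B+D)$. `true_state_counts()`,
`apparent_counts()` and `apparent_vs_true()` implement this arithmetic
exactly; `simulate_verification()` generates it mechanistically from a
latent-truth cohort, biopsying every man above the cutoff and detecting
each cancer independently with a configurable biopsy sensitivity (12-core
biopsy detects roughly 80–85% of clinically significant cancers; biopsy
specificity is treated as 1, so false-positive biopsies are not
modelled). Formal bias correction (e.g. Begg–Greenes) is out of scope:
the module quantifies the distortion, it does not undo it.

## Cross-validation and the interaction test

`tenfold_cv()` partitions the cohort into ten random folds *stratified by
case status* (at a roughly 16% case fraction, unstratified folds risk an
empty sensitivity margin); within each stratum fold sizes differ by at
most one. For each fold the adjustment models are refitted on the other
nine folds — including the case–control indicator, mirroring the main
model — and the held-out fold is scored with the training coefficients
and training-sample reference means. Means and SDs of sensitivity and
specificity over folds are reported per model and rule; on noiseless data
every fold reproduces the same numbers and all SDs are exactly zero,
which the tests use as a machinery check.

`interaction_test()` asks whether the age and BMI associations differ
between men below and at-or-above a PSA split (default 3.0 ng/ml, the
referral cutoff, with "above" meaning ≥). It refits the model in each
stratum and compares coefficients by
$Z = (\beta_{below}-\beta_{above})/\sqrt{se_{below}^2+se_{above}^2}$ with
a two-sided standard-normal p-value (a Z, not a t: stratum sizes in the
intended use are in the thousands). When a stratum contains only one
case–control level — below a 3.0 referral cutoff there are typically no
diagnosed cases — the degenerate indicator is dropped from that
stratum's fit.

## The synthetic cohort generator

`cohort_config()`/`generate_cohort()` emulate a UK screening study
population of men aged 50–69: by default 9,457 controls and 1,836 cases;
age truncated-normal (61.7, 4.94²) on [50, 69]; BMI truncated-normal
(27.2, 3.73²) on [15, 50]; and
$\ln(\mathrm{PSA}) = \mu_{status} + \beta_{age}(age-\bar{age}) +
\beta_{bmi}(bmi-\overline{bmi}) + \varepsilon$ with
$\beta_{age} = 0.126/5$ per year and $\beta_{bmi} = -0.053/5$ per kg/m².
Control PSA is centred on a median of 1.0 ng/ml and case PSA on
5.0 ng/ml; the ln-scale SDs are derived from the target interquartile
ranges (0.6–1.7 and 3.7–8.0 ng/ml) via $\sigma = \ln(q_{75}/q_{25})/1.349$,
the only choice consistent with a log-normal summarised by median and
IQR. Diagnosed cases are conditioned on PSA ≥ 3.0 ng/ml (no biopsy, no
diagnosis below the referral cutoff) and capped at 20 ng/ml (referral to
usual care above that); controls are capped at 10 ng/ml (the study's
inclusion rule). A reported mean BMI of 26.8 in one summary versus 27.2
in another, and 1,830 versus 1,836 eligible cases, are resolved in favour
of the fuller tabulation (27.2 and 1,836); likewise the 10 ng/ml cap is
applied to controls only, since case PSA summaries exceed it — both caps
are configurable for users who prefer the stricter reading. Conditioning
is enforced by redrawing whole records, with an explicit failure after
1,000 retries per record so an unreachable bound cannot hang a run.
Missingness flags (`diabetes`, `height_missing`) are generated only when
explicitly configured; the default is complete data, because imputation
is out of scope. With `latent_truth = TRUE` the conditioning is skipped
and a `true_cancer` column is carried instead, which is what
`simulate_verification()` consumes.

Two consequences of this design are worth stating plainly:

* **Truncation changes realized moments.** Truncating an age
  distribution with nominal SD 4.94 to [50, 69] yields a realized SD
  near 4.2 and a case-PSA median somewhat above 5.0 once the ≥ 3.0
  conditioning is applied. The generator's parameters are the *latent*
  ones; calibration checks therefore target the quantities that are
  robust to this (the control median, the BMI mean).
* **Conditioning biases regression slopes by design.** Selecting cases
  on their own PSA truncates the case error distribution as a function
  of the covariates, which attenuates the fitted age and BMI slopes in
  the pooled model and makes the above-cutoff stratum of the
  interaction test systematically flatter. This is a real feature of
  verification-based designs, and the test suite asserts its direction.
  For that reason the *estimator-calibration* checks (coefficient
  recovery, confidence-interval coverage) generate from the
  unconditioned model (`case_min_psa = 0`, caps at `Inf`): they are
  checks of the fitting machinery, and mixing in a known selection bias
  would test the generator's design rather than the estimator. It also
  means the synthetic default is *sharper* than real data — a real
  control arm contains undiagnosed low-PSA cancers that smooth the
  contrast — so a small interaction-test signal on default synthetic
  cohorts does not predict one on real data.

## Problem sizes and numerical choices

The shipped simulations use the study-scale cohort (11,293 men) for
single-cohort checks; 200 replicates at n = 2,000 for coverage of the
95% intervals (accepted when inside 93–97%); 500 replicates of two
250-man strata for the interaction test's type-I error (accepted within
the binomial 95% band around 5%) and 300 replicates for its power at a
3-combined-SE slope difference (expected ≈ 0.85, required > 0.8). These
sizes make every property sharp enough to fail on a real defect while
keeping the full suite fast. Ties at a threshold are impossible almost
surely in generated data but are pinned by tests (a score exactly at the
cutoff is positive). All randomness flows through explicit integer
seeds; the same configuration reproduces a cohort, a fold assignment or
a pipeline run byte for byte.

## Limitations

The generator does not emulate GP-practice matching, multi-centre
structure, self-report error in height and weight, seasonal PSA
variation, or missing-data mechanisms beyond simple Bernoulli flags; a
passing suite shows the *methods* behave as specified on data from the
stated model, not that the model captures every feature of a real
screening population. ROC curves and AUCs are deliberately absent:
under incomplete verification the sensitivities feeding them are
overestimates, so ranking models by AUC would launder the bias.
Confidence intervals for sensitivity and specificity are not produced.
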