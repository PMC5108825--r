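#' True-state cell counts under incomplete biopsy verification
#'
#' In a screening design where only men with PSA at or above the referral
#' cutoff are biopsied, the study-visible 2x2 table differs from the true
#' one. `A`/`C` are men truly with cancer at/below the cutoff, `B`/`D` men
#' truly without, and `x` is the number of cancers among the biopsied
#' (`A`) group the biopsy missed.
#'
#' @param A,B,C,D Non-negative true cell counts.
#' @param x Missed cancers among the biopsied group; `0 <= x <= A`.
#' @return A `true_state_counts` object.
#' @export
true_state_counts <- function(A, B, C, D, x = 0) {
  v <- c(A = A, B = B, C = C, D = D, x = x)
  if (anyNA(v) || any(v < 0)) stop("all counts must be non-negative")
  if (x > A) stop("x (missed cancers) cannot exceed A (biopsied cancers)")
  structure(as.list(v), class = "true_state_counts")
}

#' Study-visible counts implied by true counts
#'
#' Unbiopsied cancers (`C`) are never diagnosed, so they appear among the
#' test-negative "controls"; missed biopsies move `x` men from the
#' case-positive to the control-positive cell. The visible table is
#' therefore tp = A - x, fp = B + x, fn = 0, tn = D + C; the total count is
#' conserved.
#'
#' @param truth A [true_state_counts()] object.
#' @return A [confusion_counts()] object of apparent (study-visible) cells.
#' @examples
#' apparent_counts(true_state_counts(A = 2000, B = 1000, C = 500,
#'                                   D = 6500, x = 100))
#' @export
apparent_counts <- function(truth) {
  if (!inherits(truth, "true_state_counts"))
    stop("truth must be built with true_state_counts()")
  confusion_counts(tp = truth$A - truth$x, fp = truth$B + truth$x,
                   tn = truth$D + truth$C, fn = 0)
}

#' Apparent versus true test accuracy under verification bias
#'
#' True sensitivity is A / (A + C) and true specificity D / (B + D);
#' apparent values are computed from [apparent_counts()]. Because the
#' apparent case-negative cell is structurally zero, apparent sensitivity
#' at the verification cutoff is identically 1 whenever any case is
#' visible, so sensitivity is always overestimated when `C > 0` or
#' `x > 0`; specificity is only mildly distorted (by at most
#' `(x + C) / (B + D)`).
#'
#' @param truth A [true_state_counts()] object with `A + C > 0` and
#'   `B + D > 0`.
#' @return List with `apparent` and `true` (each sensitivity/specificity),
#'   and `bias` (apparent minus true, per metric).
#' @export
apparent_vs_true <- function(truth) {
  if (!inherits(truth, "true_state_counts"))
    stop("truth must be built with true_state_counts()")
  if (truth$A + truth$C == 0) stop("no true cancers: A + C = 0")
  if (truth$B + truth$D == 0) stop("no true non-cancers: B + D = 0")
  true <- list(sensitivity = truth$A / (truth$A + truth$C),
               specificity = truth$D / (truth$B + truth$D))
  app <- apparent_counts(truth)
  # the apparent case margin is A - x: when every biopsied cancer is
  # missed no case is ever diagnosed and apparent sensitivity is undefined
  apparent <- list(
    sensitivity = if (app$tp + app$fn > 0) {
      app$tp / (app$tp + app$fn)
    } else {
      NA_real_
    },
    specificity = app$tn / (app$tn + app$fp))
  list(apparent = apparent, true = true,
       bias = list(sensitivity = apparent$sensitivity - true$sensitivity,
                   specificity = apparent$specificity - true$specificity))
}

#' Simulate verification on a latent-truth cohort
#'
#' Takes a cohort carrying latent true cancer status (column
#' `true_cancer`, e.g. from [generate_cohort()] with
#' `latent_truth = TRUE`), "biopsies" every man with PSA at or above the
#' cutoff, and detects each true cancer among them independently with
#' probability `biopsy_sensitivity`. Biopsy specificity is taken as 1
#' (false-positive biopsies are not modelled).
#'
#' @param cohort Cohort `data.frame` with `psa` and `true_cancer`.
#' @param biopsy_cutoff PSA referral cutoff in ng/ml (default 3.0).
#' @param biopsy_sensitivity Per-cancer detection probability in \[0, 1\].
#' @param seed Integer seed for the Bernoulli detection draws.
#' @return A [true_state_counts()] object; `x` is the number of biopsied
#'   cancers the simulated biopsy failed to detect.
#' @export
simulate_verification <- function(cohort, biopsy_cutoff = 3.0,
                                  biopsy_sensitivity, seed = 1L) {
  if (!"true_cancer" %in% names(cohort))
    stop("cohort lacks latent truth (column 'true_cancer'); generate with ",
         "latent_truth = TRUE")
  if (!is.finite(biopsy_sensitivity) ||
      biopsy_sensitivity < 0 || biopsy_sensitivity > 1)
    stop("biopsy_sensitivity must lie in [0, 1]")
  set.seed(seed)
  above <- cohort$psa >= biopsy_cutoff
  cancer <- cohort$true_cancer == 1
  A <- sum(above & cancer)
  B <- sum(above & !cancer)
  C <- sum(!above & cancer)
  D <- sum(!above & !cancer)
  x <- if (A > 0) stats::rbinom(1, A, 1 - biopsy_sensitivity) else 0L
  true_state_counts(A = A, B = B, C = C, D = D, x = x)
}
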