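# Subject-level cohort realising the verification-bias worked example:
# 1900 test-positive cases, 1100 test-positive controls, 7000 test-negative
# controls, no test-negative cases (cutoff 3.0 ng/ml).
box2_cohort <- function() {
  data.frame(
    id = sprintf("B%05d", 1:10000),
    age = 60, bmi = 27,
    psa = c(rep(4, 1900), rep(4, 1100), rep(1, 7000)),
    case_status = c(rep(1, 1900), rep(0, 8100)),
    stringsAsFactors = FALSE)
}

# Small unconditioned config for recovery-style tests: the pure
# multiplicative model with no case-PSA conditioning or control cap.
unconditioned_config <- function(n_controls, n_cases, seed, ...) {
  cohort_config(n_controls = n_controls, n_cases = n_cases,
                case_min_psa = 0, control_max_psa = Inf,
                case_max_psa = Inf, seed = seed, ...)
}
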