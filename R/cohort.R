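#' Configuration for the synthetic case-control cohort generator
#'
#' Builds the parameter set from which [generate_cohort()] simulates a
#' PSA-screening case-control cohort. Defaults reproduce the calibration of a
#' large UK screening sample of men aged 50-69: ages are truncated normal
#' (mean 61.7, SD 4.94 years) on \[50, 69\], BMI truncated normal (mean 27.2,
#' SD 3.73 kg/m2) on \[15, 50\], and PSA follows a multiplicative model
#' \deqn{\ln(\mathrm{PSA}) = \mu_{status} + \beta_{age}(age - \bar{age}) +
#'   \beta_{bmi}(bmi - \overline{bmi}) + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma_{status}^2)}
#' with control median PSA 1.0 ng/ml and case median 5.0 ng/ml. The ln-scale
#' SDs are derived from the interquartile ranges 0.6-1.7 (controls) and
#' 3.7-8.0 ng/ml (cases) via \eqn{\sigma = (\ln q_{75} - \ln q_{25})/1.349},
#' the normal-quantile spacing of an IQR.
#'
#' By default the generator mirrors the screening study's design: diagnosed
#' cases require PSA >= `case_min_psa` (biopsy referral at 3.0 ng/ml) and
#' controls are capped at `control_max_psa` (10.0 ng/ml inclusion rule), both
#' enforced by rejection sampling of whole records. Cases above
#' `case_max_psa` (20 ng/ml, the referral-to-usual-care ceiling) are also
#' rejected. Set `case_min_psa = 0` and the caps to `Inf` to sample the
#' unconditioned multiplicative model.
#'
#' @param n_controls,n_cases Number of control / case records (>= 0, total
#'   > 0). Defaults 9457 and 1836.
#' @param age_mean,age_sd,age_range Age distribution (years); truncated
#'   normal on `age_range`.
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (kg/m2); truncated
#'   normal on `bmi_range`.
#' @param beta_age Per-year change in ln(PSA). Default 0.126/5.
#' @param beta_bmi Per-kg/m2 change in ln(PSA). Default -0.053/5.
#' @param control_log_median,control_log_sd ln-scale location and SD of
#'   control PSA.
#' @param case_log_median,case_log_sd ln-scale location and SD of case PSA.
#' @param case_min_psa Minimum PSA (ng/ml) a diagnosed case may have; 0
#'   disables the conditioning.
#' @param control_max_psa,case_max_psa Upper PSA caps (ng/ml); `Inf`
#'   disables.
#' @param p_diabetes,p_height_missing Optional probabilities of a `diabetes`
#'   or `height_missing` flag; when > 0 the corresponding 0/1 column is
#'   added. Default 0 (complete data).
#' @param latent_truth If `TRUE`, case/control conditioning and caps are
#'   skipped and a `true_cancer` column (copy of `case_status`) is added:
#'   the cohort then carries latent disease status for
#'   [simulate_verification()], with diagnosis left to the verification
#'   step.
#' @param seed Integer seed; the same configuration always yields the
#'   identical cohort.
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [apply_inclusion_filters()]
#' @export
cohort_config <- function(n_controls = 9457L,
                          n_cases = 1836L,
                          age_mean = 61.7, age_sd = 4.94,
                          age_range = c(50, 69),
                          bmi_mean = 27.2, bmi_sd = 3.73,
                          bmi_range = c(15, 50),
                          beta_age = 0.126 / 5,
                          beta_bmi = -0.053 / 5,
                          control_log_median = log(1.0),
                          control_log_sd = (log(1.7) - log(0.6)) / 1.349,
                          case_log_median = log(5.0),
                          case_log_sd = (log(8.0) - log(3.7)) / 1.349,
                          case_min_psa = 3.0,
                          control_max_psa = 10.0,
                          case_max_psa = 20.0,
                          p_diabetes = 0,
                          p_height_missing = 0,
                          latent_truth = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
    age_mean = age_mean, age_sd = age_sd, age_range = as.numeric(age_range),
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = as.numeric(bmi_range),
    beta_age = beta_age, beta_bmi = beta_bmi,
    control_log_median = control_log_median, control_log_sd = control_log_sd,
    case_log_median = case_log_median, case_log_sd = case_log_sd,
    case_min_psa = case_min_psa, control_max_psa = control_max_psa,
    case_max_psa = case_max_psa,
    p_diabetes = p_diabetes, p_height_missing = p_height_missing,
    latent_truth = isTRUE(latent_truth), seed = as.integer(seed)
  )
  if (cfg$n_controls < 0L || cfg$n_cases < 0L ||
      cfg$n_controls + cfg$n_cases == 0L)
    stop("n_controls and n_cases must be >= 0 with a positive total")
  if (cfg$age_sd <= 0 || cfg$bmi_sd <= 0)
    stop("age_sd and bmi_sd must be > 0")
  if (cfg$control_log_sd < 0 || cfg$case_log_sd < 0)
    stop("ln-scale SDs must be >= 0")
  for (r in list(cfg$age_range, cfg$bmi_range))
    if (length(r) != 2L || r[1] >= r[2]) stop("ranges must be ordered pairs")
  if (cfg$case_min_psa < 0) stop("case_min_psa must be >= 0")
  if (cfg$control_max_psa <= 0 || cfg$case_max_psa <= 0)
    stop("PSA caps must be > 0")
  if (!cfg$latent_truth && cfg$case_min_psa > cfg$case_max_psa)
    stop("case_min_psa exceeds case_max_psa")
  if (cfg$p_diabetes < 0 || cfg$p_diabetes > 1 ||
      cfg$p_height_missing < 0 || cfg$p_height_missing > 1)
    stop("flag probabilities must lie in [0, 1]")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "cohort_config")
}

# Exact truncated-normal draw by inverse-CDF (no rejection needed).
rtruncnorm <- function(n, mean, sd, range) {
  p <- stats::runif(n, stats::pnorm(range[1], mean, sd),
                    stats::pnorm(range[2], mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), range[1]), range[2])
}

#' Generate a synthetic PSA screening cohort
#'
#' Simulates subject-level records under the multiplicative PSA model in
#' [cohort_config()]. Records violating the arm's PSA bounds (cases below
#' `case_min_psa` or above `case_max_psa`; controls above
#' `control_max_psa`) are redrawn wholesale, with at most 1000 retries per
#' record before an explicit failure -- an unreachable bound (e.g.
#' `case_min_psa` far in the distribution's tail) therefore errors rather
#' than looping forever.
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with columns `id`, `age`, `bmi`, `psa`,
#'   `case_status`, plus `diabetes` / `height_missing` when the
#'   corresponding probability is positive and `true_cancer` when
#'   `latent_truth = TRUE`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_controls = 200, n_cases = 50,
#'                                      seed = 7))
#' median(coh$psa[coh$case_status == 0])
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be built with cohort_config()")
  set.seed(config$seed)
  arms <- list()
  for (status in c(0L, 1L)) {
    n <- if (status == 1L) config$n_cases else config$n_controls
    if (n == 0L) next
    mu <- if (status == 1L) config$case_log_median else config$control_log_median
    sigma <- if (status == 1L) config$case_log_sd else config$control_log_sd
    if (config$latent_truth) {
      lo <- 0; hi <- Inf
    } else if (status == 1L) {
      lo <- config$case_min_psa; hi <- config$case_max_psa
    } else {
      lo <- 0; hi <- config$control_max_psa
    }
    draw <- function(m) {
      age <- rtruncnorm(m, config$age_mean, config$age_sd, config$age_range)
      bmi <- rtruncnorm(m, config$bmi_mean, config$bmi_sd, config$bmi_range)
      eps <- if (sigma > 0) stats::rnorm(m, 0, sigma) else rep(0, m)
      lp <- mu + config$beta_age * (age - config$age_mean) +
        config$beta_bmi * (bmi - config$bmi_mean)
      data.frame(age = age, bmi = bmi, psa = exp(lp + eps))
    }
    d <- draw(n)
    bad <- which(d$psa < lo | d$psa > hi)
    tries <- 0L
    while (length(bad) > 0L) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop(sprintf(paste0("generate_cohort: %d %s record(s) still violate ",
                            "the PSA bounds [%g, %g] after 1000 retries; ",
                            "the truncation is likely unreachable"),
                     length(bad), if (status == 1L) "case" else "control",
                     lo, hi))
      repl <- draw(length(bad))
      d[bad, ] <- repl
      bad <- bad[repl$psa < lo | repl$psa > hi]
    }
    d$case_status <- status
    arms[[length(arms) + 1L]] <- d
  }
  out <- do.call(rbind, arms)
  rownames(out) <- NULL
  out <- data.frame(id = sprintf("S%05d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  if (config$p_diabetes > 0)
    out$diabetes <- as.integer(stats::runif(nrow(out)) < config$p_diabetes)
  if (config$p_height_missing > 0)
    out$height_missing <-
      as.integer(stats::runif(nrow(out)) < config$p_height_missing)
  if (config$latent_truth) out$true_cancer <- out$case_status
  out
}

#' Apply the study's inclusion and exclusion criteria
#'
#' Filters a cohort by, in order: age within \[50, 69\]; BMI within
#' \[15, 50\]; no diabetes (records with `diabetes = 1` or a missing
#' diabetes value are dropped; the rule is skipped when the column is
#' absent); height present (`height_missing = 1` dropped; skipped when
#' absent); and controls with PSA above `max_control_psa` dropped. Cases are
#' not subject to the PSA cap, matching a design in which case PSA summaries
#' may exceed it.
#'
#' @param cohort A cohort `data.frame` with at least `age`, `bmi`, `psa`,
#'   `case_status`.
#' @param max_control_psa Control PSA cap in ng/ml (default 10.0).
#' @param age_range,bmi_range Inclusion windows.
#' @return A list with `cohort` (the filtered table) and `exclusions`, a
#'   `data.frame` of rule names and counts removed, in application order.
#' @export
apply_inclusion_filters <- function(cohort, max_control_psa = 10.0,
                                    age_range = c(50, 69),
                                    bmi_range = c(15, 50)) {
  need <- c("age", "bmi", "psa", "case_status")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  rules <- c("age", "bmi", "diabetes", "height_missing", "control_psa")
  removed <- stats::setNames(integer(length(rules)), rules)
  drop_by <- function(keep, rule) {
    keep[is.na(keep)] <- FALSE
    removed[rule] <<- sum(!keep)
    cohort <<- cohort[keep, , drop = FALSE]
  }
  drop_by(cohort$age >= age_range[1] & cohort$age <= age_range[2], "age")
  drop_by(cohort$bmi >= bmi_range[1] & cohort$bmi <= bmi_range[2], "bmi")
  if ("diabetes" %in% names(cohort))
    drop_by(!is.na(cohort$diabetes) & cohort$diabetes == 0, "diabetes")
  if ("height_missing" %in% names(cohort))
    drop_by(is.na(cohort$height_missing) | cohort$height_missing == 0,
            "height_missing")
  drop_by(cohort$case_status == 1 | cohort$psa <= max_control_psa,
          "control_psa")
  if (nrow(cohort) == 0L)
    warning("apply_inclusion_filters: no records remain after filtering")
  rownames(cohort) <- NULL
  list(cohort = cohort,
       exclusions = data.frame(rule = rules, n_removed = unname(removed),
                               stringsAsFactors = FALSE))
}
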