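# Configuration for the synthetic multimorbidity cohort generator.

#' The 14 chronic conditions tracked in the cohort
#'
#' Column names of the binary condition flags carried by generated
#' baselines, covering the cardiometabolic, musculoskeletal, respiratory,
#' digestive, and neuropsychiatric conditions a multimorbidity survey
#' typically records.
#'
#' @format Character vector of length 14.
#' @export
chronic_conditions <- c(
  "hypertension", "diabetes", "cancer", "lung_disease", "heart_disease",
  "stroke", "mental_illness", "arthritis", "dyslipidemia", "liver_disease",
  "kidney_disease", "stomach_disease", "asthma", "memory_disorder"
)

default_comorbidity_patterns <- function() {
  low <- setNames(rep(0.08, length(chronic_conditions)), chronic_conditions)
  arthritis_stomach <- low
  arthritis_stomach[c("arthritis", "stomach_disease")] <- c(0.92, 0.85)
  arthritis_stomach["lung_disease"] <- 0.15
  cardiometabolic <- low
  cardiometabolic[c("hypertension", "heart_disease", "diabetes",
                    "dyslipidemia", "arthritis")] <- c(0.82, 0.55, 0.42, 0.48, 0.60)
  cardiometabolic["stroke"] <- 0.15
  list(
    arthritis_stomach = arthritis_stomach,
    cardiometabolic_arthritis = cardiometabolic
  )
}

default_covariate_margins <- function() {
  list(
    # age >= 45 with median near 59: 45 + Gamma(shape, scale), rounded
    age_shape = 3.2, age_scale = 4.9, age_max = 95,
    male = 0.3857,
    married = 0.8876,
    rural = 0.6314,
    education = c(primary_or_below = 0.72, middle_school = 0.18,
                  high_school_or_above = 0.10),
    retired = 0.1199,
    insured = 0.9635,
    # family size = 1 + Poisson(mean); median 3
    family_size_mean = 2.3,
    # CES-D-10 baseline level and residual SD (points, before the
    # education/retirement shifts configured in mediation_coefs)
    cesd_base = 10.3, cesd_sd = 6,
    # marginal P(no difficulty) on each of IADL and ADL chosen so the joint
    # "no difficulty on either" share is ~0.7535 under independence
    functional = c(none = 0.868, some = 0.09, severe = 0.042)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic panel generator: cohort size, wave
#' times, latent trajectory-class structure (shares and per-class polynomial
#' mean curves on the 0-10 composite-score scale), the residual spread of
#' observed scores around the class curve, the mediation structure
#' (education/retirement shift CES-D, CES-D shifts the class log-odds),
#' direct log-odds of class membership for the remaining determinants,
#' two latent comorbidity patterns over 14 chronic-condition flags, and
#' target marginal distributions for the baseline covariates.
#'
#' Defaults reproduce the cohort structure the estimators in this package
#' are designed for: 1,343 subjects observed at five waves (times 0-4), a
#' declining majority class (share 0.9144, mean `0.806 - 0.023 t`) and an
#' improving minority class (share 0.0856, mean
#' `0.896 + 0.816 t - 0.118 t^2`), residual SD 0.2 score units, and an
#' arthritis-stomach vs cardiometabolic-arthritis comorbidity split in
#' 0.3723/0.6277 proportion.
#'
#' @param n_subjects Number of subjects.
#' @param wave_times Strictly increasing numeric wave times.
#' @param class_shares Marginal trajectory-class probabilities (sum to 1);
#'   class order follows `class_polynomials`.
#' @param class_polynomials List of per-class coefficient vectors
#'   (intercept, linear, optionally quadratic) on the composite-score scale.
#' @param residual_sd Residual SD of observed scores around the class mean
#'   curve (score units, > 0).
#' @param mediation_coefs List with `a_edu` and `a_ret` (CES-D points per
#'   education level / per retirement flag) and `b` (class log-odds per
#'   CES-D point).
#' @param direct_logodds Named numeric: direct class log-odds per unit of
#'   `age`, `family_size`, `education` (0/1/2 levels) and `retirement`,
#'   centered so `class_shares` stay the marginal shares.
#' @param comorbidity_patterns List of per-pattern condition-flag
#'   probabilities (each a length-14 vector named by condition).
#' @param pattern_shares Marginal comorbidity-pattern probabilities.
#' @param pattern_coupling Log-odds shift of the second comorbidity pattern
#'   for improving-class subjects; 0 (default) makes trajectory and
#'   comorbidity classes independent.
#' @param covariate_margins List of target marginal distributions; see
#'   `default_covariate_margins()` in the package source for the fields.
#' @param indicators If `TRUE`, back-generate 21 indicator columns whose
#'   fixed-weight combination reproduces the composite score.
#' @param seed Integer seed driving all sampling.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 200, seed = 7)
#' cohort <- simulate_cohort(cfg)
cohort_config <- function(n_subjects = 1343,
                          wave_times = 0:4,
                          class_shares = c(0.9144, 0.0856),
                          class_polynomials = list(
                            declining = c(0.806, -0.023),
                            improving = c(0.896, 0.816, -0.118)
                          ),
                          residual_sd = 0.2,
                          mediation_coefs = list(a_edu = -0.231,
                                                 a_ret = -0.405,
                                                 b = -0.026),
                          direct_logodds = c(age = -0.03, family_size = -0.12,
                                             education = 0.43,
                                             retirement = 0.55),
                          comorbidity_patterns = default_comorbidity_patterns(),
                          pattern_shares = c(0.3723, 0.6277),
                          pattern_coupling = 0,
                          covariate_margins = default_covariate_margins(),
                          indicators = FALSE,
                          seed = 1L) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects <= 0) {
    stop_config("n_subjects must be a positive count")
  }
  if (any(diff(wave_times) <= 0)) {
    stop_config("wave_times must be strictly increasing")
  }
  check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) stop_config("%s must lie in [0, 1]", what)
    if (abs(sum(p) - 1) > 1e-8) stop_config("%s must sum to 1", what)
  }
  check_probs(class_shares, "class_shares")
  check_probs(pattern_shares, "pattern_shares")
  if (length(class_polynomials) != length(class_shares)) {
    stop_config("class_polynomials and class_shares must have the same length")
  }
  if (any(vapply(class_polynomials, length, 1L) > 3L)) {
    stop_config("polynomial orders above quadratic are not supported")
  }
  if (length(comorbidity_patterns) != length(pattern_shares)) {
    stop_config("comorbidity_patterns and pattern_shares must have the same length")
  }
  for (p in comorbidity_patterns) {
    if (length(p) != length(chronic_conditions) || any(p < 0 | p > 1)) {
      stop_config("each comorbidity pattern needs %d probabilities in [0, 1]",
                  length(chronic_conditions))
    }
  }
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    stop_config("residual_sd must be non-negative")
  }
  margins <- modifyList(default_covariate_margins(), covariate_margins)
  check_probs(margins$education, "education margins")
  check_probs(margins$functional, "functional (IADL/ADL) margins")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      wave_times = as.numeric(wave_times),
      class_shares = class_shares,
      class_polynomials = class_polynomials,
      residual_sd = residual_sd,
      mediation_coefs = mediation_coefs,
      direct_logodds = direct_logodds,
      comorbidity_patterns = comorbidity_patterns,
      pattern_shares = pattern_shares,
      pattern_coupling = pattern_coupling,
      covariate_margins = margins,
      indicators = isTRUE(indicators),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  subjects: %d, waves: %s\n", x$n_subjects,
              paste(x$wave_times, collapse = ", ")))
  cat(sprintf("  trajectory classes: %d (shares %s), residual sd %.3g\n",
              length(x$class_shares),
              paste(format(x$class_shares), collapse = "/"), x$residual_sd))
  cat(sprintf("  comorbidity patterns: %d (shares %s)\n",
              length(x$pattern_shares),
              paste(format(x$pattern_shares), collapse = "/")))
  cat(sprintf("  indicators: %s, seed: %d\n",
              if (x$indicators) "yes" else "no", x$seed))
  invisible(x)
}
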