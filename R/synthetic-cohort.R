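# Seeded synthetic cohort generator.
#
# Produces panels with the latent structure the downstream estimators
# assume: a baseline covariate table with configured marginals and a
# CES-D score that depends linearly on education and retirement, latent
# trajectory classes drawn from a logistic model on the determinants,
# latent comorbidity patterns over 14 chronic-condition flags (with the
# multimorbidity floor of at least two conditions per subject), and a
# per-wave composite behavior score following the class polynomial plus
# normal noise.

#' Generate baseline covariates for a synthetic cohort
#'
#' Draws one row per subject: age (>= 45), gender, marital status,
#' residence, education (three levels), retirement, insurance, family size
#' (>= 1), CES-D-10 depression score (0-30), and three-level IADL/ADL
#' difficulty categories. All covariates are sampled independently from the
#' configured margins except CES-D, whose mean is shifted by education and
#' retirement through `config$mediation_coefs$a_edu` / `a_ret` — the
#' exposure side of the generator's mediation structure.
#'
#' @param config A [cohort_config()].
#' @return Tibble with `config$n_subjects` rows.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  m <- config$covariate_margins
  n <- config$n_subjects
  set.seed(derive_seeds(config$seed, 3L)[1L])

  age <- pmin(45 + round(rgamma(n, shape = m$age_shape, scale = m$age_scale)),
              m$age_max)
  gender <- factor(ifelse(runif(n) < m$male, "male", "female"),
                   levels = c("female", "male"))
  marital <- factor(ifelse(runif(n) < m$married, "married", "other"),
                    levels = c("married", "other"))
  residence <- factor(ifelse(runif(n) < m$rural, "rural", "urban"),
                      levels = c("rural", "urban"))
  education <- factor(
    sample(names(m$education), n, replace = TRUE, prob = m$education),
    levels = names(m$education)
  )
  retirement <- as.integer(runif(n) < m$retired)
  insurance <- as.integer(runif(n) < m$insured)
  family_size <- 1L + rpois(n, m$family_size_mean)
  edu_num <- as.integer(education) - 1L
  cesd_mu <- m$cesd_base +
    config$mediation_coefs$a_edu * edu_num +
    config$mediation_coefs$a_ret * retirement
  cesd <- pmin(pmax(round(cesd_mu + rnorm(n, sd = m$cesd_sd)), 0), 30)
  flev <- names(m$functional)
  iadl <- factor(sample(flev, n, TRUE, prob = m$functional), levels = flev)
  adl <- factor(sample(flev, n, TRUE, prob = m$functional), levels = flev)

  tibble(
    id = seq_len(n),
    age = as.numeric(age), gender, marital, residence, education,
    retirement, insurance, family_size = as.numeric(family_size),
    cesd = as.numeric(cesd), iadl, adl
  )
}

#' Assign latent trajectory and comorbidity classes
#'
#' The trajectory class is drawn from a logistic model on centered age,
#' family size, education (0/1/2), retirement, and CES-D, with intercept
#' `qlogis(share of class 2)` so that when all log-odds are zero the
#' marginal class shares equal `config$class_shares`. The comorbidity
#' pattern is drawn from `config$pattern_shares`, independent of the
#' trajectory class unless `pattern_coupling` is nonzero. With more than
#' two trajectory classes configured, covariate effects must be zero and
#' classes are drawn from the marginal shares.
#'
#' @param covariates Baseline tibble from [generate_covariates()].
#' @param config The same [cohort_config()].
#' @return `covariates` with integer columns `true_trajectory_class` and
#'   `true_comorbidity_class` appended.
#' @export
assign_classes <- function(covariates, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(covariates)
  set.seed(derive_seeds(config$seed, 3L)[2L])
  k <- length(config$class_shares)
  beta <- config$direct_logodds
  b_cesd <- config$mediation_coefs$b
  if (k == 2L) {
    edu_num <- as.integer(covariates$education) - 1L
    ctr <- function(x) x - mean(x)
    eta <- qlogis(config$class_shares[2L]) +
      beta[["age"]] * ctr(covariates$age) +
      beta[["family_size"]] * ctr(covariates$family_size) +
      beta[["education"]] * ctr(edu_num) +
      beta[["retirement"]] * ctr(covariates$retirement) +
      b_cesd * ctr(covariates$cesd)
    trajectory <- 1L + rbinom(n, 1L, plogis(eta))
  } else {
    if (any(beta != 0) || b_cesd != 0) {
      stop_config("covariate effects on class membership require exactly 2 classes")
    }
    trajectory <- sample.int(k, n, replace = TRUE, prob = config$class_shares)
  }
  p2 <- config$pattern_shares
  if (length(p2) == 2L && config$pattern_coupling != 0) {
    eta_p <- qlogis(p2[2L]) + config$pattern_coupling * (trajectory == 2L)
    comorbidity <- 1L + rbinom(n, 1L, plogis(eta_p))
  } else {
    comorbidity <- sample.int(length(p2), n, replace = TRUE, prob = p2)
  }
  covariates %>%
    mutate(true_trajectory_class = as.integer(trajectory),
           true_comorbidity_class = as.integer(comorbidity))
}

#' Generate the panel of composite scores and condition flags
#'
#' Completes the synthetic cohort: chronic-condition flags are drawn
#' per-subject from the comorbidity pattern's Bernoulli probabilities,
#' redrawing until every subject carries at least two conditions (the
#' multimorbidity entry criterion); the observed composite score at each
#' wave is the class polynomial evaluated at the wave time plus
#' `Normal(0, residual_sd)` noise, clamped to the 0-10 score scale. When
#' `config$indicators` is `TRUE`, 21 standardized indicator columns are
#' back-generated so that their fixed-weight combination reproduces the
#' composite exactly.
#'
#' @param covariates Baseline tibble with class labels from
#'   [assign_classes()].
#' @param config The same [cohort_config()].
#' @return An object of class `phb_cohort`: a list with `baseline` (one
#'   row per subject, covariates + condition flags + true classes) and
#'   `panel` (one row per subject-wave: `id`, `wave`, `time`, `score`, and
#'   optionally the indicator columns), plus the generating `config`.
#' @export
generate_panel <- function(covariates, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(covariates$true_trajectory_class)) {
    stop_config("covariates must carry class labels; call assign_classes() first")
  }
  if (any(vapply(config$class_polynomials, length, 1L) > 3L)) {
    stop_config("polynomial orders above quadratic are not supported")
  }
  set.seed(derive_seeds(config$seed, 3L)[3L])
  n <- nrow(covariates)
  times <- config$wave_times

  # condition flags per comorbidity pattern, >= 2 flags enforced by redraw
  probs <- config$comorbidity_patterns
  flags <- matrix(0L, n, length(chronic_conditions),
                  dimnames = list(NULL, chronic_conditions))
  pat <- covariates$true_comorbidity_class
  for (k in seq_along(probs)) {
    rows <- which(pat == k)
    if (!length(rows)) next
    pk <- probs[[k]]
    draw <- matrix(rbinom(length(rows) * length(pk), 1L, rep(pk, each = length(rows))),
                   nrow = length(rows))
    for (iter in 1:1000) {
      short <- rowSums(draw) < 2L
      if (!any(short)) break
      draw[short, ] <- matrix(
        rbinom(sum(short) * length(pk), 1L, rep(pk, each = sum(short))),
        nrow = sum(short)
      )
    }
    short <- rowSums(draw) < 2L
    if (any(short)) { # pathological pattern probabilities: force two flags on
      for (i in which(short)) {
        on <- order(pk, decreasing = TRUE)[1:2]
        draw[i, on] <- 1L
      }
    }
    flags[rows, ] <- draw
  }
  baseline <- bind_cols(covariates, as_tibble(as.data.frame(flags)))

  # per-wave composite scores around the class polynomial
  cls <- covariates$true_trajectory_class
  mu <- vapply(times, function(t) {
    vapply(config$class_polynomials,
           function(b) sum(b * t^(seq_along(b) - 1L)), numeric(1))[cls]
  }, numeric(n))
  score <- mu + matrix(rnorm(n * length(times), sd = config$residual_sd),
                       n, length(times))
  score <- pmin(pmax(score, 0), 10)
  panel <- tibble(
    id = rep(covariates$id, times = length(times)),
    wave = rep(seq_along(times), each = n),
    time = rep(times, each = n),
    score = as.vector(score)
  ) %>% arrange(.data$id, .data$wave)

  if (config$indicators) {
    panel <- bind_cols(panel, backfill_indicators(panel$score))
  }
  structure(list(baseline = baseline, panel = panel, config = config),
            class = "phb_cohort")
}

# Back-generate 21 standardized indicator columns whose weighted sum (on
# the packaged reference weights, renormalized) equals score/10 exactly:
# start from the flat profile z = target, add zero-weighted-mean noise, and
# shrink the noise per row so every entry stays in [0, 1].
backfill_indicators <- function(score) {
  specs <- indicator_spec()
  w <- specs$ref_weight / sum(specs$ref_weight)
  m <- length(w)
  target <- pmin(pmax(score / 10, 0), 1)
  e <- matrix(runif(length(score) * m, -0.5, 0.5), ncol = m)
  d <- e - drop(e %*% w) # weighted mean removed: sum_j w_j d_ij = 0
  room <- pmin(target, 1 - target)
  amp <- apply(abs(d), 1L, max)
  s <- ifelse(amp > 0, pmin(1, room / amp), 0)
  z <- pmin(pmax(target + s * d, 0), 1) # guard floating-point drift
  colnames(z) <- specs$indicator
  as_tibble(as.data.frame(z))
}

#' Simulate a full synthetic cohort
#'
#' Convenience chain of [generate_covariates()], [assign_classes()] and
#' [generate_panel()] under one configuration and seed.
#'
#' @param config A [cohort_config()].
#' @return A `phb_cohort` object (see [generate_panel()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 100, seed = 3))
#' head(cohort$panel)
simulate_cohort <- function(config = cohort_config()) {
  covs <- generate_covariates(config)
  covs <- assign_classes(covs, config)
  generate_panel(covs, config)
}

#' @export
print.phb_cohort <- function(x, ...) {
  cat(sprintf("<phb_cohort> %d subjects x %d waves (%d conditions tracked)\n",
              nrow(x$baseline), length(x$config$wave_times),
              length(chronic_conditions)))
  invisible(x)
}
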