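test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(class_shares = c(0.6, 0.3)), "sum to 1")
  expect_error(cohort_config(wave_times = c(0, 2, 1)), "increasing")
  expect_error(cohort_config(class_polynomials = list(c(1, 1, 1, 1), c(0)),
                             class_shares = c(0.5, 0.5)), "quadratic")
  expect_error(cohort_config(pattern_shares = c(0.5, 0.6)), "sum to 1")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 120, seed = 99, indicators = TRUE)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$panel, b$panel)
  c2 <- simulate_cohort(cohort_config(n_subjects = 120, seed = 100))
  expect_false(identical(a$baseline$cesd, c2$baseline$cesd))
})

test_that("realized covariate margins track the configured targets", {
  n <- 10000
  cfg <- cohort_config(n_subjects = n, seed = 1)
  cov <- generate_covariates(cfg)
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  rural <- mean(cov$residence == "rural")
  expect_gt(rural, 0.615)
  expect_lt(rural, 0.648)
  expect_lt(abs(mean(cov$gender == "male") - 0.3857), se3(0.3857))
  expect_lt(abs(mean(cov$marital == "married") - 0.8876), se3(0.8876))
  expect_lt(abs(mean(cov$education == "primary_or_below") - 0.72), se3(0.72))
  expect_lt(abs(mean(cov$retirement) - 0.1199), se3(0.1199))
  expect_lt(abs(mean(cov$insurance) - 0.9635), se3(0.9635))
  expect_true(all(cov$cesd >= 0 & cov$cesd <= 30))
  expect_true(all(cov$family_size >= 1))
  expect_true(all(cov$age >= 45))
  expect_true(median(cov$age) >= 58 && median(cov$age) <= 60)
  expect_equal(median(cov$family_size), 3)
})

test_that("CES-D responds to education/retirement only through a_edu, a_ret", {
  cfg0 <- cohort_config(n_subjects = 10000, seed = 2,
                        mediation_coefs = list(a_edu = 0, a_ret = 0, b = 0))
  cov0 <- generate_covariates(cfg0)
  expect_lt(abs(cor(as.integer(cov0$education), cov0$cesd)), 0.03)
  cfg1 <- cohort_config(n_subjects = 10000, seed = 2,
                        mediation_coefs = list(a_edu = -3, a_ret = 0, b = 0))
  cov1 <- generate_covariates(cfg1)
  expect_lt(cor(as.integer(cov1$education), cov1$cesd), -0.1)
})

test_that("class assignment reproduces marginal shares and monotone limits", {
  n <- 20000
  cfg <- cohort_config(
    n_subjects = n, seed = 5,
    direct_logodds = c(age = 0, family_size = 0, education = 0, retirement = 0),
    mediation_coefs = list(a_edu = 0, a_ret = 0, b = 0)
  )
  cls <- assign_classes(generate_covariates(cfg), cfg)
  minority <- mean(cls$true_trajectory_class == 2L)
  expect_lt(abs(minority - 0.0856), 3 * sqrt(0.0856 * 0.9144 / n))
  pat2 <- mean(cls$true_comorbidity_class == 2L)
  expect_lt(abs(pat2 - 0.6277), 3 * sqrt(0.6277 * 0.3723 / n))

  # overwhelmingly negative CES-D effect: high-CES-D subjects never improve
  cfg_b <- cohort_config(
    n_subjects = 4000, seed = 6,
    direct_logodds = c(age = 0, family_size = 0, education = 0, retirement = 0),
    mediation_coefs = list(a_edu = 0, a_ret = 0, b = -50)
  )
  cls_b <- assign_classes(generate_covariates(cfg_b), cfg_b)
  high <- cls_b$cesd > quantile(cls_b$cesd, 0.75)
  expect_lt(mean(cls_b$true_trajectory_class[high] == 2L), 0.001)
})

test_that("marginal education-class association is positive under pure mediation", {
  cfg <- cohort_config(
    n_subjects = 20000, seed = 7,
    direct_logodds = c(age = 0, family_size = 0, education = 0, retirement = 0),
    mediation_coefs = list(a_edu = -4, a_ret = 0, b = -0.15)
  )
  cls <- assign_classes(generate_covariates(cfg), cfg)
  edu <- as.integer(cls$education) - 1L
  improving <- cls$true_trajectory_class == 2L
  expect_gt(cor(edu, improving), 0.02)
})

test_that("panels follow the class polynomials and keep the score scale", {
  cfg <- cohort_config(n_subjects = 60, seed = 3, residual_sd = 0)
  co <- simulate_cohort(cfg)
  by_class <- split(co$panel, co$baseline$true_trajectory_class[co$panel$id])
  # noiseless scores sit exactly on the generating polynomial
  t <- by_class[["1"]]$time
  expect_equal(by_class[["1"]]$score, 0.806 - 0.023 * t, tolerance = 1e-12)
  t2 <- by_class[["2"]]$time
  expect_equal(by_class[["2"]]$score, 0.896 + 0.816 * t2 - 0.118 * t2^2,
               tolerance = 1e-12)
  # quadratic class mean at t = 2 is 0.896 + 0.816*2 - 0.118*4
  expect_equal(unique(by_class[["2"]]$score[t2 == 2]), 2.056, tolerance = 1e-12)
  expect_true(all(co$panel$score >= 0 & co$panel$score <= 10))
  # balanced panel: every subject at every wave
  expect_equal(unname(table(co$panel$id)), rep(5L, 60),
               ignore_attr = TRUE)
})

test_that("every subject is multimorbid and flags follow their pattern", {
  co <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 4))
  flags <- as.matrix(co$baseline[, chronic_conditions])
  expect_true(all(rowSums(flags) >= 2))
  art_stom <- co$baseline$true_comorbidity_class == 1L
  expect_gt(mean(flags[art_stom, "arthritis"]), 0.8)
  expect_gt(mean(flags[art_stom, "stomach_disease"]), 0.75)
  expect_gt(mean(flags[!art_stom, "hypertension"]), 0.7)
})

test_that("back-generated indicators reproduce the composite exactly", {
  cfg <- cohort_config(n_subjects = 80, seed = 12, indicators = TRUE)
  co <- simulate_cohort(cfg)
  sp <- indicator_spec()
  z <- as.matrix(co$panel[, sp$indicator])
  expect_true(all(z >= 0 & z <= 1))
  recon <- 10 * drop(z %*% (sp$ref_weight / sum(sp$ref_weight)))
  expect_equal(recon, co$panel$score, tolerance = 1e-12)
})

test_that("unsupported polynomial orders are rejected at generation", {
  cfg <- cohort_config(n_subjects = 20, seed = 1)
  cfg$class_polynomials[[2]] <- c(1, 1, 1, 1) # bypass constructor check
  covs <- assign_classes(generate_covariates(cfg), cfg)
  expect_error(generate_panel(covs, cfg), "quadratic")
})
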