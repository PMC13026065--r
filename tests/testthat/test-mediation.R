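strong_mediation_config <- function(n = 1000, seed = 1, b = -0.12,
                                    a_edu = -2.5, a_ret = -3,
                                    direct = c(age = 0, family_size = 0,
                                               education = 0, retirement = 0)) {
  cohort_config(
    n_subjects = n, seed = seed,
    mediation_coefs = list(a_edu = a_edu, a_ret = a_ret, b = b),
    direct_logodds = direct
  )
}

baseline_with_class <- function(cfg) {
  co <- simulate_cohort(cfg)
  dplyr::mutate(co$baseline, trajectory_class = true_trajectory_class)
}

test_that("effects decompose exactly and products follow the two equations", {
  bl <- baseline_with_class(strong_mediation_config(seed = 5))
  fit <- fit_paths(bl)
  eff <- fit$effects
  # total = direct + indirect to machine precision, per exposure
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-14)
  # indirect = a * b recomputed from the fitted equations themselves
  a <- coef(fit$mediator_fit)[fit$exposures]
  b <- coef(fit$outcome_fit)[["cesd"]]
  expect_equal(eff$indirect, unname(a * b), tolerance = 1e-12)
  expect_equal(eff$direct, unname(coef(fit$outcome_fit)[fit$exposures]),
               tolerance = 1e-12)
  # proportion mediated is the stated ratio
  expect_equal(eff$proportion_mediated, 100 * eff$indirect / eff$total,
               tolerance = 1e-10)
})

test_that("negative a and negative b make a positive indirect effect", {
  bl <- baseline_with_class(strong_mediation_config(n = 2000, seed = 7))
  eff <- fit_paths(bl)$effects
  edu <- eff[eff$exposure == "education", ]
  expect_lt(edu$a, 0)
  expect_lt(edu$b, 0)
  expect_gt(edu$indirect, 0)
  ret <- eff[eff$exposure == "retirement", ]
  expect_gt(ret$indirect, 0)
})

test_that("y-standardization rescales the outcome-side coefficients", {
  bl <- baseline_with_class(strong_mediation_config(seed = 11))
  raw <- fit_paths(bl, scale = "raw")$effects
  std <- fit_paths(bl, scale = "ystandardized")$effects
  eta <- predict(fit_paths(bl)$outcome_fit, type = "link")
  sf <- sqrt(var(eta) + pi^2 / 3)
  expect_equal(std$direct, raw$direct / sf, tolerance = 1e-10)
  expect_equal(std$indirect, raw$indirect / sf, tolerance = 1e-10)
  # the proportion mediated is scale-free
  expect_equal(std$proportion_mediated, raw$proportion_mediated,
               tolerance = 1e-10)
})

test_that("the proportion-mediated helper reproduces printed-style ratios", {
  expect_equal(round(proportion_mediated(0.051, 0.095), 2), 65.07)
  expect_true(is.na(proportion_mediated(0.5, -0.5)))
  expect_equal(proportion_mediated(0, 0.2), 100)
})

test_that("bootstrap intervals are seeded, degenerate at one draw, and attach", {
  bl <- baseline_with_class(strong_mediation_config(n = 300, seed = 13))
  fit <- fit_paths(bl)
  one <- bootstrap_ci(fit, n_boot = 1, seed = 4)
  ci1 <- one$effects_ci
  expect_equal(ci1$conf_low, ci1$conf_high, tolerance = 1e-12)
  b1 <- bootstrap_ci(fit, n_boot = 25, seed = 9)
  b2 <- bootstrap_ci(fit, n_boot = 25, seed = 9)
  expect_identical(b1$effects_ci, b2$effects_ci)
  expect_true(all(b1$effects_ci$conf_low <= b1$effects_ci$conf_high))
  expect_identical(tidy(b1), b1$effects_ci)
})

test_that("the generating indirect effect is recovered within bootstrap CIs", {
  true_ie_covered <- sapply(1:6, function(s) {
    cfg <- strong_mediation_config(n = 800, seed = 700 + s)
    bl <- baseline_with_class(cfg)
    fit <- bootstrap_ci(fit_paths(bl), n_boot = 60, seed = s)
    ci <- fit$effects_ci
    row <- ci[ci$exposure == "education" & ci$effect == "indirect", ]
    true_ie <- -2.5 * -0.12
    row$conf_low <= true_ie && true_ie <= row$conf_high
  })
  expect_gte(mean(true_ie_covered), 5 / 6)
})

test_that("subgroup fits are independent and consistent on identical data", {
  bl <- baseline_with_class(strong_mediation_config(n = 400, seed = 17))
  bl$pattern <- rep(c("p1", "p2"), each = 200)
  # make the two subgroups literally identical
  bl[201:400, setdiff(names(bl), "pattern")] <-
    bl[1:200, setdiff(names(bl), "pattern")]
  fits <- subgroup_paths(bl)
  expect_named(fits, c("p1", "p2"))
  expect_equal(fits$p1$effects, fits$p2$effects, tolerance = 1e-10)
  eff <- attr(fits, "effects")
  expect_setequal(unique(eff$subgroup), c("p1", "p2"))
  small <- bl[c(1:30, 201:400), ]
  expect_warning(subgroup_paths(small), "only 30 subjects")
})

test_that("degenerate inputs are rejected", {
  bl <- baseline_with_class(strong_mediation_config(n = 200, seed = 19))
  bl$cesd <- 5
  expect_error(fit_paths(bl), "constant")
  bl2 <- baseline_with_class(strong_mediation_config(n = 200, seed = 19))
  expect_error(fit_paths(bl2, mediator = "nope"), "missing")
})
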