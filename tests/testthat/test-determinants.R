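test_that("chi-square comparisons match hand calculations", {
  d <- tibble::tibble(
    grp = rep(1:2, each = 20),
    v = factor(c(rep("a", 10), rep("b", 10), rep("a", 10), rep("b", 10)))
  )
  res <- compare_groups(d, "grp", categorical = "v", continuous = character(0))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # 2x2 closed form: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  d2 <- tibble::tibble(
    grp = rep(1:2, each = 30),
    v = factor(c(rep("a", 20), rep("b", 10), rep("a", 10), rep("b", 20)))
  )
  res2 <- compare_groups(d2, "grp", categorical = "v",
                         continuous = character(0))
  expect_equal(res2$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4,
               tolerance = 1e-10)
  expect_equal(res2$statistic, 6.667, tolerance = 1e-3)
})

test_that("rank-sum reports the smaller group's rank sum with mid-ranks", {
  d <- tibble::tibble(grp = rep(1:2, each = 3), v = c(1, 2, 3, 4, 5, 6))
  res <- compare_groups(d, "grp", categorical = character(0), continuous = "v")
  expect_equal(res$statistic, 6) # ranks 1+2+3 in the first group
  # enumeration oracle: 1/20 one-sided tail, 1/10 two-sided
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # ties handled through mid-ranks
  dt <- tibble::tibble(grp = c(1, 1, 1, 2, 2), v = c(1, 2, 2, 2, 3))
  rest <- compare_groups(dt, "grp", categorical = character(0),
                         continuous = "v")
  reft <- suppressWarnings(wilcox.test(v ~ grp, data = dt, exact = FALSE,
                                       correct = FALSE))
  expect_equal(rest$p_value, reft$p.value, tolerance = 1e-12)
})

test_that("sparse contingency tables are flagged, not refused", {
  d <- tibble::tibble(
    grp = rep(1:2, c(40, 2)),
    v = factor(c(rep("a", 39), "b", "a", "b"))
  )
  res <- compare_groups(d, "grp", categorical = "v", continuous = character(0))
  expect_equal(res$note, "expected cell < 1")
})

test_that("a single binary predictor recovers the closed-form log odds ratio", {
  # exposure/outcome counts a=30, b=10, c=20, d=40
  d <- tibble::tibble(
    x = c(rep(1, 40), rep(0, 60)),
    y = c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  )
  fit <- fit_logistic(d, class_col = "y", predictors = "x")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "x"], log(6), tolerance = 1e-8)
  expect_equal(td$odds_ratio[td$term == "x"], 6, tolerance = 1e-7)
})

test_that("the fitted coefficients agree with a brute-force Newton oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 120
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = runif(n),
      g = factor(sample(c("u", "v", "w"), n, TRUE))
    )
    eta <- 0.3 + 0.8 * d$x1 - 0.5 * d$x2 + 0.6 * (d$g == "v")
    d$y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(d, class_col = "y", predictors = c("x1", "x2", "g"))
    x <- model.matrix(~ x1 + x2 + g, d)
    expect_equal(unname(coef(fit$fit)), unname(oracle_logistic_newton(x, d$y)),
                 tolerance = 1e-6)
  }
})

test_that("null predictors give near-zero coefficients and McFadden R2", {
  set.seed(29)
  d <- tibble::tibble(x1 = rnorm(4000), x2 = rnorm(4000),
                      y = rbinom(4000, 1, 0.3))
  fit <- fit_logistic(d, class_col = "y", predictors = c("x1", "x2"))
  td <- tidy(fit)
  expect_true(all(abs(td$estimate[-1]) < 0.1))
  expect_lt(glance(fit)$mcfadden_r2, 0.005)
})

test_that("recoding a binary predictor's reference flips its sign exactly", {
  set.seed(31)
  d <- tibble::tibble(x = factor(sample(c("a", "b"), 300, TRUE)))
  d$y <- rbinom(300, 1, plogis(0.7 * (d$x == "b")))
  f1 <- tidy(fit_logistic(d, "y", "x"))
  d2 <- dplyr::mutate(d, x = stats::relevel(x, "b"))
  f2 <- tidy(fit_logistic(d2, "y", "x"))
  expect_equal(f1$estimate[2], -f2$estimate[2], tolerance = 1e-8)
})

test_that("pathological designs are detected by name", {
  set.seed(37)
  d <- tibble::tibble(x1 = rnorm(50))
  d$x2 <- 2 * d$x1
  d$y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(d, "y", c("x1", "x2")), "collinear")
  sep <- tibble::tibble(x = c(rep(0, 25), rep(1, 25)),
                        y = c(rep(0, 25), rep(1, 25)))
  expect_warning(fit_logistic(sep, "y", "x"), "separation")
})

test_that("coefficient recovery sits inside the Wald interval most of the time", {
  hits <- sapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 500
    d <- tibble::tibble(x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-1 + 0.8 * d$x))
    td <- tidy(fit_logistic(d, "y", "x"))
    log(td$conf_low[2]) <= 0.8 && 0.8 <= log(td$conf_high[2])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the univariate screen feeds the multivariable model", {
  co <- simulate_cohort(cohort_config(
    n_subjects = 1200, seed = 8,
    direct_logodds = c(age = 0, family_size = 0, education = 2, retirement = 0),
    mediation_coefs = list(a_edu = 0, a_ret = 0, b = 0)
  ))
  bl <- dplyr::mutate(co$baseline, trajectory_class = true_trajectory_class)
  screen <- compare_groups(bl, "trajectory_class")
  expect_true("education" %in% screen$variable[screen$significant])
  fit <- fit_logistic(bl, "trajectory_class")
  expect_true(any(grepl("education", fit$predictors)))
})
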