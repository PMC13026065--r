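spec2 <- function(directions = c("positive", "positive")) {
  tibble::tibble(
    indicator = paste0("x", seq_along(directions)),
    direction = directions,
    dimension = "health habits",
    ref_weight = 100 / length(directions)
  )
}

test_that("min-max standardization honours direction and flags constants", {
  d <- tibble::tibble(x1 = c(1, 3, 5), x2 = c(0, 1, 0), x3 = c(2, 2, 2))
  sp <- spec2(c("positive", "negative", "positive"))
  sp$indicator <- c("x1", "x2", "x3")
  z <- standardize_indicators(d, sp)
  expect_equal(z$x1, c(0, 0.5, 1))
  expect_equal(z$x2, c(1, 0, 1)) # negative indicator: direction flipped
  expect_equal(z$x3, c(0, 0, 0))
  expect_equal(attr(z, "constant"), c(x1 = FALSE, x2 = FALSE, x3 = TRUE))
  expect_error(standardize_indicators(tibble::tibble(x1 = c(1, NA), x2 = 1:2), spec2()),
               "missing")
  expect_error(standardize_indicators(d[0, ], sp), "2 rows")
})

test_that("entropy weights match symmetry, mirror-image and zero-column cases", {
  # identical non-constant columns share the weight
  z <- cbind(a = c(0, 0.4, 1), b = c(0, 0.4, 1))
  expect_equal(entropy_weights(z)$weight, c(0.5, 0.5))
  # mirror-image columns have equal entropy, hence equal weights
  z3 <- cbind(a = c(0, 0.5, 1), b = c(1, 0.5, 0))
  w3 <- entropy_weights(z3)
  expect_equal(w3$weight, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(w3$entropy[1], w3$entropy[2], tolerance = 1e-12)
  # all-zero column carries no information
  z0 <- cbind(a = c(0, 1, 0.3), b = c(0, 0, 0))
  w0 <- entropy_weights(z0)
  expect_equal(w0$weight[2], 0)
  expect_equal(sum(w0$weight), 1)
  expect_error(entropy_weights(cbind(a = c(0, 0), b = c(0, 0))), "constant")
})

test_that("vectorized weights agree with the literal step-by-step oracle", {
  set.seed(42)
  for (rep in 1:20) {
    z <- matrix(runif(15), 5, 3)
    # put each column on the standardized [0,1] range
    z <- apply(z, 2, function(x) (x - min(x)) / (max(x) - min(x)))
    w <- entropy_weights(z)$weight
    expect_equal(w, oracle_entropy_weights(z), tolerance = 1e-10)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("increasing affine transforms of a raw indicator change nothing", {
  set.seed(7)
  d <- tibble::tibble(x1 = runif(30, 2, 9), x2 = rnorm(30))
  sp <- spec2()
  w1 <- attr(score_behaviors(d, sp), "weights")
  s1 <- score_behaviors(d, sp)$score
  d2 <- dplyr::mutate(d, x1 = 3.7 * x1 + 11)
  w2 <- attr(score_behaviors(d2, sp), "weights")
  s2 <- score_behaviors(d2, sp)$score
  expect_equal(w1$weight, w2$weight, tolerance = 1e-12)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("a constant indicator gets weight 0 and leaves the rest untouched", {
  set.seed(8)
  d <- tibble::tibble(x1 = runif(25), x2 = runif(25))
  sp <- spec2()
  base <- attr(score_behaviors(d, sp), "weights")
  d3 <- dplyr::mutate(d, x3 = 5)
  sp3 <- spec2(rep("positive", 3))
  aug <- attr(score_behaviors(d3, sp3), "weights")
  expect_equal(aug$weight[3], 0)
  expect_equal(aug$weight[1:2], base$weight, tolerance = 1e-12)
  expect_equal(score_behaviors(d3, sp3)$score, score_behaviors(d, sp)$score,
               tolerance = 1e-12)
})

test_that("composite scores are the rescaled weighted sum", {
  z <- rbind(rep(1, 3), rep(0, 3))
  w <- c(0.2, 0.3, 0.5)
  expect_equal(composite_scores(z, w), c(10, 0))
  expect_equal(composite_scores(rbind(c(1, 0)), c(0.25, 0.75)), 2.5)
  expect_error(composite_scores(z, c(0.5, 0.5)), "match")
})

test_that("the packaged indicator set matches its published structure", {
  sp <- indicator_spec()
  expect_equal(nrow(sp), 21L)
  expect_equal(sum(sp$ref_weight), 100, tolerance = 1e-9)
  expect_identical(sp$indicator[sp$direction == "negative"],
                   c("smoking", "drinking"))
  expect_setequal(unique(sp$dimension),
                  c("health exercise", "health habits",
                    "health social interaction"))
})

test_that("fixed-weight scoring spans 0-10 and isolates single indicators", {
  sp <- indicator_spec()
  best <- worst <- setNames(as.list(rep(0, 21)), sp$indicator)
  for (i in seq_len(21)) {
    mx <- if (sp$indicator[i] %in% c("smoking", "drinking")) 1 else 4
    best[[i]] <- if (sp$direction[i] == "positive") mx else 0
    worst[[i]] <- if (sp$direction[i] == "positive") 0 else mx
  }
  d <- dplyr::bind_rows(tibble::as_tibble(best), tibble::as_tibble(worst))
  out <- score_with_fixed_weights(d, sp)
  expect_equal(out$score, c(10, 0), tolerance = 1e-12)
  # standardized profile with only vigorous activity at its maximum
  z <- matrix(0, 1, 21, dimnames = list(NULL, sp$indicator))
  z[1, "vigorous_activity"] <- 1
  expect_equal(composite_scores(z, sp$ref_weight / sum(sp$ref_weight)),
               10 * 0.0048, tolerance = 1e-12)
})
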