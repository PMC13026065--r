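# Determinants of trajectory-class membership: univariate between-group
# tests (chi-square for categorical variables, Wilcoxon rank-sum for
# continuous/ordinal ones) and a multivariable logistic regression with the
# declining (class 1) trajectory as the reference outcome.

default_baseline_vars <- function() {
  list(
    categorical = c("gender", "marital", "residence", "education",
                    "retirement", "insurance", "iadl", "adl"),
    continuous = c("age", "family_size", "cesd")
  )
}

#' Univariate comparisons between trajectory groups
#'
#' For each baseline variable, compares its distribution across the two
#' trajectory classes: categorical variables by Pearson chi-square on the
#' contingency table (no continuity correction), continuous or ordinal
#' variables (age, family size, CES-D) by the Wilcoxon rank-sum test using
#' the normal approximation with mid-ranks and tie correction. The reported
#' rank-sum statistic is the sum of ranks in the smaller group (first group
#' on ties). All p-values are two-sided.
#'
#' @param data Baseline table, one row per subject.
#' @param class_col Name of the class-label column (two classes).
#' @param categorical,continuous Character vectors of variable names; the
#'   defaults cover the standard baseline covariate set and are filtered to
#'   columns present in `data`.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, `significant`, `note` (flags any expected
#'   contingency cell below 1).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 300, seed = 4))
#' baseline <- dplyr::mutate(cohort$baseline,
#'                           trajectory_class = true_trajectory_class)
#' compare_groups(baseline, "trajectory_class")
compare_groups <- function(data, class_col = "trajectory_class",
                           categorical = NULL, continuous = NULL,
                           alpha = 0.05) {
  if (!class_col %in% names(data)) {
    stop_config("class column '%s' not found", class_col)
  }
  g <- factor(data[[class_col]])
  if (nlevels(g) != 2L) stop_config("compare_groups needs exactly 2 classes")
  defaults <- default_baseline_vars()
  categorical <- categorical %||% intersect(defaults$categorical, names(data))
  continuous <- continuous %||% intersect(defaults$continuous, names(data))

  cat_rows <- purrr::map_dfr(categorical, function(v) {
    tab <- table(data[[v]], g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(variable = v, test = "chi-square",
           statistic = unname(ct$statistic), p_value = ct$p.value,
           note = if (any(expected < 1)) "expected cell < 1" else NA_character_)
  })
  con_rows <- purrr::map_dfr(continuous, function(v) {
    x <- split(data[[v]], g)
    sizes <- lengths(x)
    small <- which.min(sizes) # smaller group; first group on ties
    r <- rank(unlist(x, use.names = FALSE)) # mid-ranks
    idx <- rep(seq_along(x), sizes)
    stat <- sum(r[idx == small])
    wt <- suppressWarnings(
      wilcox.test(x[[1L]], x[[2L]], exact = FALSE, correct = FALSE)
    )
    tibble(variable = v, test = "rank-sum", statistic = stat,
           p_value = wt$p.value, note = NA_character_)
  })
  bind_rows(cat_rows, con_rows) %>%
    mutate(significant = .data$p_value < alpha) %>%
    select("variable", "test", "statistic", "p_value", "significant", "note")
}

#' Multivariable logistic regression for trajectory-class membership
#'
#' Fits class membership (improving vs declining, declining as the
#' reference outcome) on the selected predictors by maximum likelihood.
#' Categorical predictors are expanded against their factor reference
#' levels (the generator codes education with `primary_or_below` and
#' residence with `rural` as reference). By default the predictor set is
#' every variable flagged significant by [compare_groups()], mirroring the
#' univariate-screen entry rule; pass `predictors` to override.
#'
#' @param data Baseline table.
#' @param class_col Binary class column; the higher level is modeled as the
#'   event.
#' @param predictors Character vector of predictor columns, or `NULL` to
#'   screen with [compare_groups()] at `alpha`.
#' @param alpha Screening threshold when `predictors` is `NULL`.
#' @return An object of class `phb_logit` wrapping the underlying fit, with
#'   [tidy()] returning log-odds, odds ratios, Wald standard errors, 95%
#'   CIs and p-values, and [glance()] the log-likelihoods and McFadden
#'   pseudo-R².
#' @export
fit_logistic <- function(data, class_col = "trajectory_class",
                         predictors = NULL, alpha = 0.05) {
  g <- factor(data[[class_col]])
  if (nlevels(g) != 2L) stop_config("outcome must have exactly 2 classes")
  y <- as.integer(g) - 1L
  if (is.null(predictors)) {
    screen <- compare_groups(data, class_col, alpha = alpha)
    predictors <- screen$variable[screen$significant]
    if (!length(predictors)) {
      stop_config("no predictor passed the univariate screen; supply `predictors`")
    }
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop_config("predictor column(s) missing: %s",
                                paste(miss, collapse = ", "))
  df <- data.frame(.y = y, data[predictors], check.names = FALSE)
  # collinearity check on the expanded design
  x <- model.matrix(as.formula(paste(".y ~", paste(sprintf("`%s`", predictors),
                                                   collapse = " + "))), df)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop_config("collinear predictor column(s): %s",
                paste(dropped, collapse = ", "))
  }
  fit <- glm(as.formula(paste(".y ~", paste(sprintf("`%s`", predictors),
                                            collapse = " + "))),
             data = df, family = binomial(),
             control = glm.control(epsilon = 1e-10, maxit = 100))
  separation <- !fit$converged || any(abs(coef(fit)) > 15)
  if (separation) {
    rlang::warn("possible complete separation: diverging coefficient detected")
  }
  null_ll <- as.numeric(logLik(glm(.y ~ 1, data = df, family = binomial())))
  structure(list(
    fit = fit, predictors = predictors, loglik = as.numeric(logLik(fit)),
    null_loglik = null_ll,
    mcfadden_r2 = 1 - as.numeric(logLik(fit)) / null_ll,
    separation = separation, outcome_levels = levels(g)
  ), class = "phb_logit")
}

#' @export
print.phb_logit <- function(x, ...) {
  cat(sprintf("<phb_logit> outcome %s vs %s (reference), %d predictors\n",
              x$outcome_levels[2L], x$outcome_levels[1L], length(x$predictors)))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.phb_logit <- function(x, conf_level = 0.95, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est - zq * se)),
    conf_high = exp(unname(est + zq * se)),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se)))
  )
}

#' @export
glance.phb_logit <- function(x, ...) {
  tibble(
    loglik = x$loglik, null_loglik = x$null_loglik,
    mcfadden_r2 = x$mcfadden_r2, n = length(x$fit$y),
    separation = x$separation
  )
}

#' Forest-style plot of odds ratios
#'
#' Odds ratios with 95% Wald intervals for every non-intercept term of a
#' logistic determinant fit, on a log scale with the null line at 1.
#'
#' @param object A `phb_logit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phb_logit <- function(object, ...) {
  td <- tidy(object) %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
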