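# Path analysis with a single mediator: a linear equation for the mediator
# (CES-D regressed on the exposures) and a logistic equation for the
# outcome (trajectory class on exposures + mediator). For each exposure the
# indirect effect is the product of its mediator-equation coefficient and
# the mediator's outcome-equation coefficient, the direct effect is its own
# outcome-equation coefficient, total = direct + indirect, and the
# proportion mediated is 100 * indirect / total. Because the outcome
# equation is logistic while the mediator equation is linear, coefficients
# can optionally be y-standardized (divided by the implied latent-response
# SD of the logistic equation) before products are formed.

path_design <- function(data, exposures) {
  d <- data
  for (v in exposures) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      d[[v]] <- as.numeric(factor(d[[v]])) - 1 # ordinal 0/1/2 coding
    }
  }
  d
}

path_effects <- function(data, outcome01, exposures, mediator, scale) {
  med_f <- as.formula(paste(sprintf("`%s`", mediator), "~",
                            paste(sprintf("`%s`", exposures), collapse = " + ")))
  med_fit <- lm(med_f, data = data)
  out_f <- as.formula(paste(".y ~",
                            paste(sprintf("`%s`", c(exposures, mediator)),
                                  collapse = " + ")))
  data$.y <- outcome01
  out_fit <- glm(out_f, data = data, family = binomial(),
                 control = glm.control(epsilon = 1e-10, maxit = 100))
  oc <- coef(out_fit)
  scale_factor <- 1
  if (scale == "ystandardized") {
    eta <- predict(out_fit, type = "link")
    scale_factor <- sqrt(stats::var(eta) + pi^2 / 3)
  }
  b <- oc[[mediator]] / scale_factor
  a <- coef(med_fit)[exposures]
  de <- oc[exposures] / scale_factor
  ie <- a * b
  total <- de + ie
  list(
    mediator_fit = med_fit, outcome_fit = out_fit,
    effects = tibble(
      exposure = exposures,
      a = unname(a), b = unname(rep(b, length(exposures))),
      direct = unname(de), indirect = unname(ie), total = unname(total),
      proportion_mediated = ifelse(total != 0, 100 * unname(ie) / unname(total),
                                   NA_real_)
    ),
    converged = out_fit$converged,
    separation = !out_fit$converged || any(abs(oc) > 15)
  )
}

#' Fit mediation paths from determinants to trajectory class
#'
#' Fits the two path equations — mediator (default CES-D) on the exposures
#' by ordinary least squares, and class membership (improving vs declining)
#' on exposures plus mediator by logistic maximum likelihood — and reports,
#' per exposure, the direct effect (outcome-equation coefficient), the
#' indirect effect through the mediator (product of coefficients), the
#' total effect and the proportion mediated. Factor exposures are converted
#' to 0-based ordinal scores so each contributes a single path coefficient.
#'
#' @param data Baseline table containing exposures, mediator, and the class
#'   column.
#' @param class_col Binary class column; the higher level is the event.
#' @param exposures Exposure columns; defaults to age, family size,
#'   education and retirement.
#' @param mediator Mediator column (linear equation), default `"cesd"`.
#' @param scale `"raw"` reports logit-scale outcome coefficients;
#'   `"ystandardized"` divides outcome-equation coefficients by the implied
#'   latent-response SD before forming products.
#' @param subgroup Optional label stored with the fit.
#' @return An object of class `phb_paths`: `effects` tibble, both fitted
#'   equations, and bookkeeping. [tidy()] returns the effects table.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 400, seed = 9))
#' baseline <- dplyr::mutate(cohort$baseline,
#'                           trajectory_class = true_trajectory_class)
#' tidy(fit_paths(baseline))
fit_paths <- function(data, class_col = "trajectory_class",
                      exposures = c("age", "family_size", "education",
                                    "retirement"),
                      mediator = "cesd",
                      scale = c("raw", "ystandardized"),
                      subgroup = "all") {
  scale <- match.arg(scale)
  miss <- setdiff(c(exposures, mediator, class_col), names(data))
  if (length(miss)) stop_config("column(s) missing: %s",
                                paste(miss, collapse = ", "))
  if (length(unique(data[[mediator]])) < 2L) {
    stop_config("mediator '%s' is constant", mediator)
  }
  g <- factor(data[[class_col]])
  if (nlevels(g) != 2L) stop_config("outcome must have exactly 2 classes")
  d <- path_design(as_tibble(data), exposures)
  pe <- path_effects(d, as.integer(g) - 1L, exposures, mediator, scale)
  if (pe$separation) {
    rlang::warn("possible separation in the outcome equation")
  }
  structure(list(
    effects = pe$effects, mediator_fit = pe$mediator_fit,
    outcome_fit = pe$outcome_fit, exposures = exposures,
    mediator = mediator, class_col = class_col, scale = scale,
    subgroup = subgroup, n = nrow(d), data = d, outcome01 = as.integer(g) - 1L
  ), class = "phb_paths")
}

#' Bootstrap confidence intervals for mediation effects
#'
#' Subject-level nonparametric bootstrap of a fitted path model: subjects
#' are resampled with replacement, both equations refit, and 2.5/97.5
#' percentile intervals formed for every direct, indirect and total effect
#' and proportion mediated. Replicates whose outcome equation fails to
#' converge are dropped and counted; more than 10% dropped is an error.
#'
#' @param paths A `phb_paths` fit.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Interval coverage (default 0.95).
#' @return The `phb_paths` object with `conf_low`/`conf_high` columns
#'   merged into `effects` (long layout: one row per exposure and effect
#'   type) stored as `effects_ci`, plus `n_boot_used`.
#' @export
bootstrap_ci <- function(paths, n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(paths, "phb_paths"))
  if (n_boot < 1L) stop_config("n_boot must be >= 1")
  seeds <- derive_seeds(seed, 1L)
  set.seed(seeds)
  n <- paths$n
  draws <- vector("list", n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      path_effects(paths$data[idx, , drop = FALSE], paths$outcome01[idx],
                   paths$exposures, paths$mediator, paths$scale),
      error = function(e) NULL
    )
    if (is.null(rep_fit) || !rep_fit$converged) {
      dropped <- dropped + 1L
      next
    }
    draws[[b]] <- rep_fit$effects
  }
  if (dropped > 0.1 * n_boot) {
    stop_config("%d of %d bootstrap replicates failed to converge", dropped,
                n_boot)
  }
  draws <- bind_rows(draws[!vapply(draws, is.null, logical(1))])
  alpha <- (1 - conf_level) / 2
  ci <- draws %>%
    tidyr::pivot_longer(c("direct", "indirect", "total",
                          "proportion_mediated"),
                        names_to = "effect", values_to = "value") %>%
    group_by(.data$exposure, .data$effect) %>%
    summarise(conf_low = quantile(.data$value, alpha, na.rm = TRUE,
                                  names = FALSE),
              conf_high = quantile(.data$value, 1 - alpha, na.rm = TRUE,
                                   names = FALSE),
              .groups = "drop")
  est <- paths$effects %>%
    tidyr::pivot_longer(c("direct", "indirect", "total",
                          "proportion_mediated"),
                        names_to = "effect", values_to = "estimate") %>%
    select("exposure", "effect", "estimate")
  paths$effects_ci <- left_join(est, ci, by = c("exposure", "effect"))
  paths$n_boot_used <- n_boot - dropped
  paths$conf_level <- conf_level
  paths
}

#' Mediation paths within comorbidity subgroups
#'
#' Runs [fit_paths()] independently within each comorbidity pattern,
#' warning when a subgroup has fewer than 50 subjects.
#'
#' @param data Baseline table with class and pattern columns.
#' @param pattern_col Column of comorbidity-pattern labels.
#' @param ... Passed to [fit_paths()].
#' @return Named list of `phb_paths` fits, one per pattern; the combined
#'   effects table (with a `subgroup` column) is attached as the `effects`
#'   attribute.
#' @export
subgroup_paths <- function(data, pattern_col = "pattern", ...) {
  if (!pattern_col %in% names(data)) {
    stop_config("pattern column '%s' not found", pattern_col)
  }
  groups <- split(as_tibble(data), data[[pattern_col]])
  fits <- purrr::imap(groups, function(d, nm) {
    if (nrow(d) < 50L) {
      rlang::warn(sprintf("subgroup '%s' has only %d subjects", nm, nrow(d)))
    }
    fit_paths(d, subgroup = nm, ...)
  })
  eff <- purrr::imap_dfr(fits, function(f, nm) mutate(f$effects, subgroup = nm))
  attr(fits, "effects") <- eff
  fits
}

#' Proportion of an effect that is mediated
#'
#' The share of the total effect carried by the indirect path:
#' `100 * indirect / (direct + indirect)`, in percent. Undefined (NA) when
#' the total effect is zero.
#'
#' @param direct,indirect Direct and indirect effect estimates.
#' @return Percent mediated.
#' @export
#' @examples
#' proportion_mediated(0.051, 0.095) # 65.07
proportion_mediated <- function(direct, indirect) {
  total <- direct + indirect
  ifelse(total != 0, 100 * indirect / total, NA_real_)
}

#' @export
print.phb_paths <- function(x, ...) {
  cat(sprintf("<phb_paths> subgroup '%s', n = %d, mediator = %s, scale = %s\n",
              x$subgroup, x$n, x$mediator, x$scale))
  print(x$effects, n = Inf)
  invisible(x)
}

#' @export
tidy.phb_paths <- function(x, ...) {
  if (!is.null(x$effects_ci)) x$effects_ci else x$effects
}

#' @export
glance.phb_paths <- function(x, ...) {
  tibble(
    subgroup = x$subgroup, n = x$n, scale = x$scale,
    mediator_r2 = summary(x$mediator_fit)$r.squared,
    outcome_loglik = as.numeric(logLik(x$outcome_fit)),
    n_boot = x$n_boot_used %||% NA_integer_
  )
}

#' Plot direct and indirect effects per exposure
#'
#' Dodged bars of direct vs indirect effect for every exposure in a path
#' fit — the at-a-glance decomposition of each determinant's total effect.
#'
#' @param object A `phb_paths`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phb_paths <- function(object, ...) {
  td <- object$effects %>%
    tidyr::pivot_longer(c("direct", "indirect"), names_to = "effect",
                        values_to = "value")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$exposure, y = .data$value,
                                   fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "effect on class membership", fill = NULL) +
    ggplot2::theme_minimal()
}
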