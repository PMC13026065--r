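# Exact Shapley-value decomposition of a model fit statistic across
# predictors. Each "player" is one predictor (a categorical predictor
# enters with all of its levels as a single player); the value of a
# coalition is the fit statistic of the model using exactly those
# predictors, and each player's Shapley value averages its marginal
# contribution over all coalitions with the exact combinatorial weights.

# value functions: McFadden pseudo-R2 for a binary outcome (empty model
# = intercept-only = 0), classical R2 for a continuous outcome
value_mcfadden <- function(data, outcome, cols) {
  df <- data.frame(.y = data[[outcome]], data[cols], check.names = FALSE)
  null_ll <- as.numeric(logLik(glm(.y ~ 1, data = df, family = binomial())))
  if (!length(cols)) return(0)
  f <- as.formula(paste(".y ~", paste(sprintf("`%s`", cols), collapse = " + ")))
  fit <- glm(f, data = df, family = binomial(),
             control = glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    rlang::warn(sprintf("subset fit {%s} did not converge",
                        paste(cols, collapse = ",")))
  }
  1 - as.numeric(logLik(fit)) / null_ll
}

value_r2 <- function(data, outcome, cols) {
  if (!length(cols)) return(0)
  df <- data.frame(.y = data[[outcome]], data[cols], check.names = FALSE)
  f <- as.formula(paste(".y ~", paste(sprintf("`%s`", cols), collapse = " + ")))
  summary(lm(f, data = df))$r.squared
}

#' Exact Shapley decomposition of model fit across predictors
#'
#' Allocates a model's fit statistic across predictors by the Shapley
#' value: for every one of the `2^p` predictor coalitions the model is
#' refit and its fit statistic evaluated, and player `j` receives
#' `phi_j = sum over S not containing j of |S|! (p-|S|-1)! / p! *
#' [v(S + j) - v(S)]`. The allocation satisfies efficiency
#' (`sum(phi) = v(full) - v(empty)`), symmetry and the dummy-player axiom.
#' Percent contributions are `100 phi_j / v(full)`.
#'
#' @param data Data frame with the outcome and all player columns.
#' @param outcome Outcome column: binary 0/1 (or 2-level factor) for
#'   `value = "mcfadden"`, numeric for `value = "r2"`.
#' @param players Character vector of predictor columns (each one player),
#'   or a named list mapping player names to column sets.
#' @param value Fit statistic: McFadden pseudo-R² of a logistic fit
#'   (default) or linear-model R².
#' @return An object of class `phb_shapley`; [tidy()] returns one row per
#'   player with `phi` and `percent`, sorted by descending percent.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200))
#' d$y <- rbinom(200, 1, plogis(d$x1))
#' tidy(shapley_decompose(d, "y", c("x1", "x2")))
shapley_decompose <- function(data, outcome, players,
                              value = c("mcfadden", "r2")) {
  value <- match.arg(value)
  if (!is.list(players)) players <- setNames(as.list(players), players)
  p <- length(players)
  if (p < 1L) stop_config("at least one player is required")
  if (p > 12L) {
    stop_config(paste("exact enumeration supports at most 12 players;",
                      "reduce the player set (sampling approximation not provided)"))
  }
  miss <- setdiff(unique(unlist(players)), names(data))
  if (length(miss)) stop_config("player column(s) missing: %s",
                                paste(miss, collapse = ", "))
  g <- data[[outcome]]
  if (value == "mcfadden") {
    gf <- factor(g)
    if (nlevels(gf) != 2L) stop_config("mcfadden value needs a binary outcome")
    data[[outcome]] <- as.integer(gf) - 1L
  }
  vfun <- switch(value, mcfadden = value_mcfadden, r2 = value_r2)

  # value of every coalition, indexed by bitmask
  masks <- 0:(2^p - 1L)
  vals <- vapply(masks, function(m) {
    members <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    vfun(data, outcome, unlist(players[members], use.names = FALSE))
  }, numeric(1))

  size <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L),
                 numeric(1))
  lf <- lfactorial(0:p)
  phi <- vapply(seq_len(p), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- size[without + 1L]
    wgt <- exp(lf[s + 1L] + lf[p - s] - lf[p + 1L]) # |S|!(p-|S|-1)!/p!
    sum(wgt * (vals[bitwOr(without, bit) + 1L] - vals[without + 1L]))
  }, numeric(1))

  v_full <- vals[length(vals)]
  structure(list(
    players = names(players), phi = setNames(phi, names(players)),
    percent = setNames(100 * phi / v_full, names(players)),
    value_function = value, v_full = v_full, v_empty = vals[1L],
    n = nrow(data)
  ), class = "phb_shapley")
}

#' @export
print.phb_shapley <- function(x, ...) {
  cat(sprintf("<phb_shapley> %s decomposition over %d players (v(full) = %.4f)\n",
              x$value_function, length(x$players), x$v_full))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.phb_shapley <- function(x, ...) {
  tibble(player = x$players, phi = unname(x$phi),
         percent = unname(x$percent)) %>%
    arrange(desc(.data$percent))
}

#' @export
glance.phb_shapley <- function(x, ...) {
  tibble(value_function = x$value_function, v_full = x$v_full,
         n_players = length(x$players), n = x$n)
}

#' Ranked contribution report per trajectory class
#'
#' Runs a one-vs-rest Shapley decomposition of the class-membership model
#' for each trajectory class and reports each determinant's percent
#' contribution, sorted within class, percentages rounded to 2 decimals.
#'
#' @param data Baseline table with a class column.
#' @param class_col Class-label column (any number of classes).
#' @param players Player definition as in [shapley_decompose()].
#' @param ... Passed to [shapley_decompose()].
#' @return Tibble with columns `class`, `player`, `phi`, `percent`.
#' @export
contribution_report <- function(data, class_col = "trajectory_class",
                                players, ...) {
  classes <- sort(unique(data[[class_col]]))
  purrr::map_dfr(classes, function(cl) {
    d <- data
    d$.one_vs_rest <- as.integer(d[[class_col]] == cl)
    dec <- shapley_decompose(d, ".one_vs_rest", players, ...)
    tidy(dec) %>%
      mutate(class = cl, percent = round(.data$percent, 2)) %>%
      select("class", "player", "phi", "percent")
  })
}

#' Bar chart of Shapley percent contributions
#'
#' @param object A `phb_shapley`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phb_shapley <- function(object, ...) {
  td <- tidy(object)
  td$player <- factor(td$player, levels = rev(td$player))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$percent, y = .data$player)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "contribution to model fit (%)", y = NULL) +
    ggplot2::theme_minimal()
}
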