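# Entropy-weight composite scoring of proactive health behavior indicators.
#
# The composite score aggregates 21 behavior indicators spanning three
# dimensions (health exercise, health habits, health social interaction).
# Weights are objective: indicators whose standardized values are more
# dispersed across the sample carry less information entropy and receive
# larger weights.

#' Indicator specification for the proactive health behavior composite
#'
#' Returns the default set of 21 behavior indicators used to build the
#' composite proactive-health-behavior score: mild/moderate/vigorous physical
#' activity, smoking and drinking (the only two negative-direction
#' indicators), sleep and nap habits, and paired participation/frequency
#' items for eight kinds of social activity. Each indicator carries a
#' direction (`"positive"` or `"negative"`), a dimension label, and a
#' published reference weight in percent (summing to 100) that can be used
#' to score new data on a fixed weighting instead of refitting entropy
#' weights.
#'
#' @return A tibble with columns `indicator`, `direction`, `dimension`,
#'   and `ref_weight` (percent).
#' @export
#' @examples
#' spec <- indicator_spec()
#' sum(spec$ref_weight) # 100
indicator_spec <- function() {
  path <- system.file("extdata", "indicator_spec.csv", package = "phbtraj",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    indicator = readr::col_character(),
    direction = readr::col_character(),
    dimension = readr::col_character(),
    ref_weight = readr::col_double()
  ))
}

#' Min-max standardization of behavior indicators
#'
#' Rescales every indicator column to \[0, 1\], separately honouring the
#' indicator's direction: positive indicators map through
#' `(x - min) / (max - min)` so larger raw values score higher, negative
#' indicators (smoking, drinking) through `(max - x) / (max - min)` so
#' abstaining scores higher. Constant columns carry no ranking information;
#' they are set to 0 and flagged in the `constant` attribute.
#'
#' Missing values are a contract violation (the analysis is complete-case
#' by design) and raise an error.
#'
#' @param data A data frame whose indicator columns are numeric.
#' @param specs Indicator specification tibble (see [indicator_spec()]);
#'   `specs$indicator` names the columns to standardize.
#' @return A tibble of standardized values with one column per indicator,
#'   carrying a logical `constant` attribute naming degenerate columns.
#' @export
standardize_indicators <- function(data, specs = indicator_spec()) {
  cols <- specs$indicator
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_config("indicator column(s) missing from data: %s",
                paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(data[cols])
  if (nrow(x) < 2L) stop_config("standardization needs at least 2 rows")
  if (anyNA(x)) {
    stop_config("missing indicator values: complete cases are required")
  }
  rng_min <- apply(x, 2L, min)
  rng_max <- apply(x, 2L, max)
  span <- rng_max - rng_min
  constant <- span == 0
  span[constant] <- 1 # avoid 0/0; constant columns are zeroed below
  z <- sweep(sweep(x, 2L, rng_min, "-"), 2L, span, "/")
  neg <- specs$direction == "negative"
  z[, neg] <- 1 - z[, neg, drop = FALSE]
  z[, constant] <- 0
  out <- as_tibble(as.data.frame(z))
  attr(out, "constant") <- setNames(constant, cols)
  out
}

#' Entropy weights for standardized indicators
#'
#' Computes one weight per indicator from a standardized matrix: the share
#' matrix `p_ij = z_ij / sum_i z_ij`, per-indicator entropy
#' `e_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), redundancy
#' `d_j = 1 - e_j`, and weights `w_j = d_j / sum_j d_j`. Indicators whose
#' standardized column is identically zero carry no information and get
#' weight 0.
#'
#' @param z Standardized indicator matrix or data frame, entries in \[0, 1\].
#' @return A tibble with columns `indicator`, `entropy`, `redundancy`,
#'   `weight` (weights sum to 1).
#' @export
entropy_weights <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) stop_config("entropy weights need at least 2 rows")
  csum <- colSums(z)
  zero_col <- csum == 0
  if (all(zero_col)) {
    stop_config("all indicator columns are constant: no information to weight")
  }
  p <- sweep(z, 2L, ifelse(zero_col, 1, csum), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(n)
  e[zero_col] <- 1 # zero-information column
  d <- 1 - e
  w <- d / sum(d)
  tibble(
    indicator = colnames(z) %||% paste0("ind_", seq_along(e)),
    entropy = unname(e),
    redundancy = unname(d),
    weight = unname(w)
  )
}

#' Composite proactive health behavior scores
#'
#' Forms the weighted sum `s_i = sum_j w_j z_ij` of standardized indicators
#' and expands it by 10, yielding a score on the 0-10 scale (higher = more
#' proactive behavior).
#'
#' @param z Standardized indicator matrix or data frame.
#' @param weights Either the tibble returned by [entropy_weights()] or a
#'   bare numeric vector of weights summing to 1, in column order of `z`.
#' @return Numeric vector of scores in \[0, 10\], one per row of `z`.
#' @export
composite_scores <- function(z, weights) {
  z <- as.matrix(z)
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  if (length(w) != ncol(z)) {
    stop_config("weight length (%d) does not match indicator count (%d)",
                length(w), ncol(z))
  }
  drop(z %*% w) * 10
}

#' Score behavior panels with the entropy weight method
#'
#' One-call wrapper: standardizes the indicator columns of `data`, fits
#' entropy weights on the pooled rows (all subject-waves together, so one
#' weight set applies to every wave), and returns the input with a `score`
#' column on the 0-10 scale. Set `weights = "reference"` to skip the
#' entropy fit and apply the published per-indicator weights instead
#' (renormalized from percent to sum 1), which is how new data are scored
#' on an existing weighting.
#'
#' @param data Data frame holding the indicator columns (long format, one
#'   row per subject-wave).
#' @param specs Indicator specification (see [indicator_spec()]).
#' @param weights `"fit"` (default) to estimate entropy weights from `data`,
#'   `"reference"` to use `specs$ref_weight`, or a numeric vector.
#' @return `data` as a tibble with a `score` column appended; the weight
#'   table is attached as the `weights` attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 50, indicators = TRUE))
#' scored <- score_behaviors(cohort$panel)
#' attr(scored, "weights")
score_behaviors <- function(data, specs = indicator_spec(),
                            weights = c("fit", "reference")) {
  z <- standardize_indicators(data, specs)
  if (is.numeric(weights)) {
    w <- weights / sum(weights)
    wtab <- tibble(indicator = specs$indicator, weight = w)
  } else {
    weights <- match.arg(weights)
    wtab <- if (weights == "fit") {
      entropy_weights(z)
    } else {
      tibble(indicator = specs$indicator,
             weight = specs$ref_weight / sum(specs$ref_weight))
    }
  }
  out <- as_tibble(data)
  out$score <- composite_scores(z, wtab$weight)
  attr(out, "weights") <- wtab
  out
}

#' Score on the published fixed weights
#'
#' Convenience wrapper for [score_behaviors()] with `weights = "reference"`:
#' standardizes the 21 indicator columns and applies the published weights
#' (percent, renormalized to sum 1). Use this to score new data on the
#' study weighting rather than refitting entropy weights.
#'
#' @inheritParams score_behaviors
#' @return `data` as a tibble with a `score` column.
#' @export
score_with_fixed_weights <- function(data, specs = indicator_spec()) {
  score_behaviors(data, specs, weights = "reference")
}
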