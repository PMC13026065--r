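# Group-based trajectory modeling: finite mixtures of polynomial-in-time
# mean curves with a pooled normal residual, estimated by EM on a balanced
# panel of composite scores. Class labels are canonicalized by ascending
# intercept so "class 1" is always the lowest-starting trajectory.

# reshape a long panel into a subjects x waves score matrix; panel must be
# balanced (every subject at every wave) — the completers-only design
panel_matrix <- function(data, id = "id", time = "time", score = "score") {
  need <- c(id, time, score)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_config("panel is missing column(s): %s",
                                paste(miss, collapse = ", "))
  if (anyNA(data[[score]])) stop_config("missing scores: complete cases required")
  times <- sort(unique(data[[time]]))
  wide <- tidyr::pivot_wider(
    as_tibble(data[need]),
    names_from = dplyr::all_of(time), values_from = dplyr::all_of(score)
  )
  y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(y)) stop_config("unbalanced panel: every subject must be observed at every wave")
  if (ncol(y) < 2L) stop_config("at least 2 waves are required")
  list(ids = wide[[1L]], times = times, y = y)
}

gbtm_estep <- function(y, xs, beta, pi_k, sigma) {
  n <- nrow(y); tt <- ncol(y); k <- length(pi_k)
  lj <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mu <- drop(xs[[j]] %*% beta[[j]])
    rss <- rowSums(sweep(y, 2L, mu, "-")^2)
    lj[, j] <- log(pi_k[j]) - tt / 2 * log(2 * pi * sigma^2) - rss / (2 * sigma^2)
  }
  list(posterior = posterior_from_logjoint(lj), loglik = sum(row_logsumexp(lj)))
}

gbtm_mstep <- function(y, xs, w) {
  n <- nrow(y); tt <- ncol(y); k <- ncol(w)
  beta <- vector("list", k)
  rss_tot <- 0
  for (j in seq_len(k)) {
    sw <- sum(w[, j])
    ybar <- colSums(w[, j] * y) / sw # weighted mean profile over waves
    x <- xs[[j]]
    beta[[j]] <- drop(solve(crossprod(x), crossprod(x, ybar)))
    mu <- drop(x %*% beta[[j]])
    rss_tot <- rss_tot + sum(w[, j] * rowSums(sweep(y, 2L, mu, "-")^2))
  }
  sigma <- sqrt(max(rss_tot / (n * tt), 1e-12))
  list(beta = beta, pi_k = colMeans(w), sigma = sigma)
}

# initial hard assignment: k-means on per-subject OLS (intercept, slope)
gbtm_init <- function(y, times, k, start_seed, jitter) {
  n <- nrow(y)
  x1 <- cbind(1, times)
  ab <- t(solve(crossprod(x1), crossprod(x1, t(y)))) # n x 2 per-subject fits
  set.seed(start_seed)
  if (k == 1L) return(matrix(1, n, 1L))
  feats <- scale(ab)
  if (jitter) feats <- feats + matrix(rnorm(length(feats), sd = 0.5), nrow = n)
  cl <- tryCatch(kmeans(feats, centers = k, nstart = 5L)$cluster,
                 error = function(e) sample.int(k, n, replace = TRUE))
  w <- matrix(1e-3, n, k)
  w[cbind(seq_len(n), cl)] <- 1
  w / rowSums(w)
}

#' Fit a group-based trajectory model
#'
#' Estimates a `k`-class finite mixture in which class `j`'s composite
#' score follows a degree-`orders[j]` polynomial in time plus normal noise
#' with a residual SD pooled across classes. Estimation is EM on the
#' subject-level likelihood (each subject's score vector is conditionally
#' independent across waves given the class), started from k-means on
#' per-subject intercept/slope fits with `n_starts` seeded restarts; the
#' best restart by log-likelihood is kept. Classes are relabeled by
#' ascending intercept.
#'
#' @param data Long panel with one row per subject-wave.
#' @param k Number of trajectory classes (>= 1).
#' @param orders Polynomial order per class, each in 0:2; recycled to
#'   length `k`.
#' @param id,time,score Column names in `data`.
#' @param n_starts Number of EM restarts.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param seed Integer seed for initialization.
#' @return An object of class `gbtm_fit` with elements `beta` (per-class
#'   coefficient vectors), `pi` (mixing proportions), `sigma`, `posterior`,
#'   `loglik`, `converged`, information criteria (`aic`, `bic`, `abic`),
#'   `entropy` (relative-entropy classification index), `class_shares`
#'   (modal shares) and `avepp` (average posterior probability among
#'   subjects assigned to each class).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 150, seed = 2))
#' fit <- fit_gbtm(cohort$panel, k = 2, orders = c(1, 2), n_starts = 3)
#' glance(fit)
fit_gbtm <- function(data, k, orders = 2L, id = "id", time = "time",
                     score = "score", n_starts = 10L, max_iter = 500L,
                     tol = 1e-8, seed = 1L) {
  if (k < 1L) stop_config("k must be >= 1")
  orders <- rep_len(as.integer(orders), k)
  if (any(orders < 0L | orders > 2L)) {
    stop_config("polynomial orders must be in 0:2")
  }
  pm <- panel_matrix(data, id, time, score)
  y <- pm$y; times <- pm$times; n <- nrow(y)
  xs <- lapply(orders, function(o) outer(times, 0:o, "^"))
  seeds <- derive_seeds(seed, max(n_starts, 1L))

  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    w <- gbtm_init(y, times, k, seeds[s], jitter = s > 1L)
    fit <- gbtm_mstep(y, xs, w)
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- gbtm_estep(y, xs, fit$beta, fit$pi_k, fit$sigma)
      trace <- c(trace, es$loglik)
      if (es$loglik - ll_old < tol && it > 1L) { converged <- TRUE; break }
      ll_old <- es$loglik
      fit <- gbtm_mstep(y, xs, es$posterior)
    }
    es <- gbtm_estep(y, xs, fit$beta, fit$pi_k, fit$sigma)
    cand <- list(fit = fit, posterior = es$posterior, loglik = es$loglik,
                 converged = converged, n_iter = length(trace),
                 loglik_trace = trace)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }

  # canonical labels: ascending intercept
  ord <- order(vapply(best$fit$beta, `[`, numeric(1), 1L))
  beta <- best$fit$beta[ord]
  pi_k <- best$fit$pi_k[ord]
  orders <- orders[ord]
  posterior <- best$posterior[, ord, drop = FALSE]
  if (any(pi_k < 1e-6)) {
    rlang::warn("degenerate fit: a class has vanishing mixing proportion")
  }
  if (!best$converged) {
    rlang::warn(sprintf("EM did not converge within %d iterations", max_iter))
  }

  q <- sum(orders + 1L) + (k - 1L) + 1L
  ic <- information_criteria(best$loglik, q, n)
  modal <- max.col(posterior, ties.method = "first")
  shares <- tabulate(modal, nbins = k) / n
  avepp <- vapply(seq_len(k), function(j) {
    if (any(modal == j)) mean(posterior[modal == j, j]) else NA_real_
  }, numeric(1))

  structure(list(
    beta = setNames(beta, paste0("class", seq_len(k))),
    pi = pi_k, sigma = best$fit$sigma, orders = orders, k = k,
    posterior = posterior, modal = modal, ids = pm$ids, times = times,
    n = n, q = q, loglik = best$loglik, aic = ic$aic, bic = ic$bic,
    abic = ic$abic, entropy = relative_entropy(posterior),
    class_shares = shares, avepp = avepp,
    converged = best$converged, n_iter = best$n_iter,
    loglik_trace = best$loglik_trace, y = y
  ), class = "gbtm_fit")
}

#' Selection metrics of a trajectory fit
#'
#' One-row summary used to compare candidate models: information criteria
#' (AIC/BIC/aBIC, lower is better), the relative-entropy classification
#' index (higher is better; 1 for a single class), the smallest modal class
#' share, and the smallest average posterior probability.
#'
#' @param fit A `gbtm_fit`.
#' @return A one-row tibble.
#' @export
selection_metrics <- function(fit) {
  stopifnot(inherits(fit, "gbtm_fit"))
  tibble(
    k = fit$k, orders = paste(fit$orders, collapse = "/"),
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic, abic = fit$abic,
    entropy = fit$entropy, min_share = min(fit$class_shares),
    min_avepp = min(fit$avepp), converged = fit$converged
  )
}

#' Adequacy rules for a trajectory solution
#'
#' Checks the two conventional adequacy rules: every class's modal share is
#' at least `min_share` (default 5%) and every class's average posterior
#' probability of assignment exceeds `min_avepp` (default 0.7).
#'
#' @param fit A `gbtm_fit`.
#' @param min_share Minimum class share.
#' @param min_avepp Minimum average posterior probability.
#' @return A tibble with one row per rule (`rule`, `value`, `threshold`,
#'   `pass`); the `adequate` attribute gives the conjunction.
#' @export
adequacy_check <- function(fit, min_share = 0.05, min_avepp = 0.7) {
  stopifnot(inherits(fit, "gbtm_fit"))
  out <- tibble(
    rule = c("min_class_share", "min_avepp"),
    value = c(min(fit$class_shares), min(fit$avepp)),
    threshold = c(min_share, min_avepp),
    pass = c(min(fit$class_shares) >= min_share, min(fit$avepp) > min_avepp)
  )
  attr(out, "adequate") <- all(out$pass)
  out
}

#' Scan candidate trajectory models
#'
#' Fits every candidate class count (and per-class polynomial orders),
#' collects selection metrics and adequacy flags, and recommends the
#' adequate candidate with the lowest BIC (ties resolved toward fewer
#' classes). If no candidate is adequate the lowest-BIC candidate overall
#' is recommended.
#'
#' @param data Long panel (see [fit_gbtm()]).
#' @param candidates List of candidates, each a list with elements `k` and
#'   `orders`; defaults to quadratic classes for `k` in `k_range`.
#' @param k_range Class counts used to build default candidates.
#' @param order Common polynomial order for default candidates.
#' @param ... Passed to [fit_gbtm()] (`n_starts`, `seed`, ...).
#' @return A tibble with one row per candidate and a logical `recommended`
#'   column; fitted objects are attached as the `fits` attribute.
#' @export
scan_models <- function(data, candidates = NULL, k_range = 1:3, order = 2L, ...) {
  if (is.null(candidates)) {
    candidates <- lapply(k_range, function(k) list(k = k, orders = order))
  }
  fits <- lapply(candidates, function(cand) {
    fit_gbtm(data, k = cand$k, orders = cand$orders, ...)
  })
  tab <- purrr::map_dfr(fits, selection_metrics)
  adequate <- vapply(fits, function(f) attr(adequacy_check(f), "adequate"),
                     logical(1))
  tab$adequate <- adequate
  pool <- if (any(adequate)) which(adequate) else seq_along(fits)
  ranked <- pool[order(tab$bic[pool], tab$k[pool])]
  tab$recommended <- seq_len(nrow(tab)) == ranked[1L]
  attr(tab, "fits") <- fits
  tab
}

#' Modal trajectory-class assignment
#'
#' Assigns each subject to the class with the highest posterior
#' probability, ties broken toward the lower class index. Class indices
#' follow the fit's canonical (ascending-intercept) order.
#'
#' @param fit A `gbtm_fit`.
#' @return Tibble with columns `id`, `trajectory_class`, `posterior`.
#' @export
assign_trajectories <- function(fit) {
  stopifnot(inherits(fit, "gbtm_fit"))
  tibble(
    id = fit$ids,
    trajectory_class = fit$modal,
    posterior = fit$posterior[cbind(seq_len(fit$n), fit$modal)]
  )
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf("<gbtm_fit> %d classes, %d subjects, %d waves\n",
              x$k, x$n, length(x$times)))
  for (j in seq_len(x$k)) {
    cat(sprintf("  class %d (share %.3f, avepp %.3f): %s\n", j,
                x$class_shares[j], x$avepp[j],
                paste(sprintf("%.3f", x$beta[[j]]), collapse = ", ")))
  }
  cat(sprintf("  loglik %.2f, BIC %.2f, entropy %.3f, sigma %.3f\n",
              x$loglik, x$bic, x$entropy, x$sigma))
  invisible(x)
}

#' @export
tidy.gbtm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(j) {
    tibble(
      class = j,
      term = c("intercept", "linear", "quadratic")[seq_along(x$beta[[j]])],
      estimate = unname(x$beta[[j]])
    )
  })
}

#' @export
glance.gbtm_fit <- function(x, ...) {
  tibble(
    k = x$k, loglik = x$loglik, aic = x$aic, bic = x$bic, abic = x$abic,
    entropy = x$entropy, sigma = x$sigma, min_share = min(x$class_shares),
    min_avepp = min(x$avepp), converged = x$converged
  )
}

#' @export
augment.gbtm_fit <- function(x, ...) {
  post <- as_tibble(as.data.frame(x$posterior))
  names(post) <- paste0(".posterior_", seq_len(x$k))
  bind_cols(tibble(id = x$ids, .class = x$modal), post)
}

#' Plot fitted trajectory mean curves
#'
#' Draws each class's fitted polynomial mean curve over time together with
#' the observed class-mean score per wave (points), classes colored and
#' labeled with their modal shares.
#'
#' @param object A `gbtm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbtm_fit <- function(object, ...) {
  tgrid <- seq(min(object$times), max(object$times), length.out = 80)
  curves <- purrr::map_dfr(seq_len(object$k), function(j) {
    b <- object$beta[[j]]
    tibble(class = sprintf("class %d (%.1f%%)", j, 100 * object$class_shares[j]),
           time = tgrid,
           mean = colSums(b * t(outer(tgrid, seq_along(b) - 1L, "^"))))
  })
  obs <- purrr::map_dfr(seq_len(object$k), function(j) {
    rows <- object$modal == j
    tibble(class = sprintf("class %d (%.1f%%)", j, 100 * object$class_shares[j]),
           time = object$times,
           mean = colMeans(object$y[rows, , drop = FALSE]))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$mean,
                                       colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point(data = obs, size = 2) +
    ggplot2::labs(x = "wave time", y = "composite behavior score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
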