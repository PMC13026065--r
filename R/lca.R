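# Latent class analysis of binary chronic-condition indicators under
# conditional independence, fit by EM, with a parametric bootstrap
# likelihood-ratio test for the number of classes and a rule-based mapping
# of fitted classes onto named comorbidity patterns.

as_binary_matrix <- function(flags) {
  x <- as.matrix(as.data.frame(flags))
  if (anyNA(x)) stop_config("missing condition flags: complete cases required")
  if (!all(x %in% c(0, 1))) stop_config("condition flags must be binary 0/1")
  storage.mode(x) <- "double"
  x
}

lca_estep <- function(y, rho, pi_k) {
  # log f_ik = sum_j y log rho + (1-y) log(1-rho), vectorized per class
  lj <- y %*% t(log(rho)) + (1 - y) %*% t(log(1 - rho))
  lj <- sweep(lj, 2L, log(pi_k), "+")
  list(posterior = posterior_from_logjoint(lj), loglik = sum(row_logsumexp(lj)))
}

lca_mstep <- function(y, w, clamp = 1e-6) {
  sw <- colSums(w)
  rho <- t(w) %*% y / sw
  rho <- pmin(pmax(rho, clamp), 1 - clamp)
  list(rho = rho, pi_k = sw / nrow(y))
}

#' Fit a latent class model to binary condition flags
#'
#' EM estimation of a `k`-class mixture in which the 14 (or any number of)
#' binary condition indicators are independent within class, each with a
#' class-conditional endorsement probability. Endorsement probabilities are
#' clamped to `[1e-6, 1 - 1e-6]` to keep the likelihood off the boundary,
#' and classes are relabeled by descending class probability.
#'
#' @param flags Binary matrix or data frame (subjects x conditions).
#' @param k Number of latent classes.
#' @param n_starts Seeded EM restarts; best log-likelihood kept.
#' @param seed Integer seed.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `lca_fit`: `rho` (k x items endorsement
#'   probabilities), `pi` (class probabilities), `posterior`, `loglik`,
#'   `aic`/`bic`/`abic`, `entropy`, `class_shares`, `converged`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 300, seed = 5))
#' flags <- cohort$baseline[, chronic_conditions]
#' fit <- fit_lca(flags, k = 2, n_starts = 3, seed = 1)
#' glance(fit)
fit_lca <- function(flags, k, n_starts = 10L, seed = 1L, tol = 1e-8,
                    max_iter = 1000L) {
  y <- as_binary_matrix(flags)
  n <- nrow(y); jn <- ncol(y)
  if (k < 1L) stop_config("k must be >= 1")
  if (k >= n) stop_config("k must be smaller than the number of subjects")
  if (k > 2^jn) stop_config("k exceeds the number of distinct response patterns")
  seeds <- derive_seeds(seed, max(n_starts, 1L))

  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    set.seed(seeds[s])
    rho <- matrix(runif(k * jn, 0.15, 0.85), k, jn)
    if (k == 1L) rho <- matrix(pmin(pmax(colMeans(y), 1e-6), 1 - 1e-6), 1L, jn)
    pi_k <- rep(1 / k, k)
    ll_old <- -Inf; converged <- FALSE; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      es <- lca_estep(y, rho, pi_k)
      trace <- c(trace, es$loglik)
      if (es$loglik - ll_old < tol && it > 1L) { converged <- TRUE; break }
      ll_old <- es$loglik
      ms <- lca_mstep(y, es$posterior)
      rho <- ms$rho; pi_k <- ms$pi_k
    }
    es <- lca_estep(y, rho, pi_k)
    cand <- list(rho = rho, pi_k = pi_k, posterior = es$posterior,
                 loglik = es$loglik, converged = converged,
                 n_iter = length(trace), loglik_trace = trace)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }

  ord <- order(best$pi_k, decreasing = TRUE) # canonical: descending pi
  rho <- best$rho[ord, , drop = FALSE]
  colnames(rho) <- colnames(y)
  pi_k <- best$pi_k[ord]
  posterior <- best$posterior[, ord, drop = FALSE]
  modal <- max.col(posterior, ties.method = "first")
  q <- k * jn + (k - 1L)
  ic <- information_criteria(best$loglik, q, n)

  structure(list(
    rho = rho, pi = pi_k, posterior = posterior, modal = modal,
    k = k, n = n, n_items = jn, q = q, loglik = best$loglik,
    aic = ic$aic, bic = ic$bic, abic = ic$abic,
    entropy = relative_entropy(posterior),
    class_shares = tabulate(modal, nbins = k) / n,
    converged = best$converged, n_iter = best$n_iter,
    loglik_trace = best$loglik_trace,
    items = colnames(y) %||% paste0("item_", seq_len(jn))
  ), class = "lca_fit")
}

#' Bootstrap likelihood-ratio test for the number of latent classes
#'
#' Tests `k` classes against `k - 1` with a parametric bootstrap: the
#' observed statistic is `2 (lnL_k - lnL_{k-1})`; `n_boot` datasets are
#' simulated from the fitted `(k-1)`-class model, both models are refit on
#' each, and the p-value is `(1 + #[boot >= observed]) / (n_boot + 1)`.
#'
#' @param flags Binary matrix or data frame.
#' @param k Number of classes under the alternative (>= 2).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param n_starts,max_iter,tol Passed to [fit_lca()] (restarts are reduced
#'   on replicates for speed; the null-model simulation draws use the
#'   fitted probabilities).
#' @return An object of class `blrt_result`: `observed_lrt`, `p_value`,
#'   `boot_lrts`, `n_boot`, plus both observed-data fits.
#' @export
blrt <- function(flags, k, n_boot = 99L, seed = 1L, n_starts = 5L,
                 max_iter = 500L, tol = 1e-6) {
  if (k < 2L) stop_config("blrt needs k >= 2")
  if (n_boot < 1L) stop_config("n_boot must be >= 1")
  y <- as_binary_matrix(flags)
  seeds <- derive_seeds(seed, n_boot + 2L)
  fit0 <- fit_lca(y, k - 1L, n_starts = n_starts, seed = seeds[1L],
                  max_iter = max_iter, tol = tol)
  fit1 <- fit_lca(y, k, n_starts = n_starts, seed = seeds[2L],
                  max_iter = max_iter, tol = tol)
  observed <- 2 * (fit1$loglik - fit0$loglik)

  n <- nrow(y); jn <- ncol(y)
  boot_lrts <- vapply(seq_len(n_boot), function(b) {
    set.seed(seeds[b + 2L])
    cls <- sample.int(fit0$k, n, replace = TRUE, prob = fit0$pi)
    p <- fit0$rho[cls, , drop = FALSE]
    yb <- matrix(rbinom(n * jn, 1L, p), n, jn)
    f0 <- fit_lca(yb, k - 1L, n_starts = max(2L, n_starts %/% 2L),
                  seed = seeds[b + 2L], max_iter = max_iter, tol = tol)
    f1 <- fit_lca(yb, k, n_starts = max(2L, n_starts %/% 2L),
                  seed = seeds[b + 2L] + 1L, max_iter = max_iter, tol = tol)
    2 * (f1$loglik - f0$loglik)
  }, numeric(1))

  p_value <- (1 + sum(boot_lrts >= observed)) / (n_boot + 1)
  structure(list(
    observed_lrt = observed, boot_lrts = boot_lrts, n_boot = n_boot,
    p_value = p_value, fit_null = fit0, fit_alt = fit1, k = k
  ), class = "blrt_result")
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("<blrt_result> %d vs %d classes: LRT = %.3f, p = %.4f (%d replicates)\n",
              x$k, x$k - 1L, x$observed_lrt, x$p_value, x$n_boot))
  invisible(x)
}

#' Map latent classes to named comorbidity patterns
#'
#' Labels each fitted class with the pattern rule whose condition set has
#' the highest mean endorsement probability in that class, provided that
#' mean clears `threshold`; otherwise the class is labeled `"other"`.
#' Several classes may map to one pattern (pattern merging). Exact ties are
#' broken deterministically by rule order, and tied candidates are reported
#' in the `candidates` column.
#'
#' @param fit An `lca_fit`.
#' @param rules Named list: each element is a character vector of condition
#'   names defining a pattern. Defaults to the two patterns the generator
#'   emulates (arthritis-stomach and cardiometabolic-arthritis).
#' @param threshold Minimum mean endorsement probability for a match.
#' @return Tibble with one row per class: `class`, `share`, `pattern`,
#'   `match_score`, `candidates`.
#' @export
map_patterns <- function(fit,
                         rules = list(
                           arthritis_stomach = c("arthritis", "stomach_disease"),
                           cardiometabolic_arthritis = c("hypertension",
                                                         "diabetes",
                                                         "heart_disease",
                                                         "dyslipidemia",
                                                         "arthritis")
                         ),
                         threshold = 0.5) {
  stopifnot(inherits(fit, "lca_fit"))
  bad <- setdiff(unique(unlist(rules)), fit$items)
  if (length(bad)) stop_config("pattern rules name unknown condition(s): %s",
                               paste(bad, collapse = ", "))
  purrr::map_dfr(seq_len(fit$k), function(j) {
    scores <- vapply(rules, function(conds) mean(fit$rho[j, conds]), numeric(1))
    best <- max(scores)
    hits <- names(rules)[abs(scores - best) < 1e-12]
    label <- if (best >= threshold) hits[1L] else "other"
    tibble(class = j, share = fit$class_shares[j], pattern = label,
           match_score = best, candidates = paste(hits, collapse = ";"))
  })
}

#' Per-subject comorbidity pattern labels
#'
#' Combines modal class assignment with [map_patterns()] to label every
#' subject with a named comorbidity pattern.
#'
#' @param fit An `lca_fit`.
#' @param ids Optional subject ids (defaults to row numbers).
#' @param ... Passed to [map_patterns()].
#' @return Tibble with columns `id`, `comorbidity_class`, `pattern`.
#' @export
assign_patterns <- function(fit, ids = NULL, ...) {
  pm <- map_patterns(fit, ...)
  tibble(
    id = ids %||% seq_len(fit$n),
    comorbidity_class = fit$modal,
    pattern = pm$pattern[fit$modal]
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> %d classes on %d items, %d subjects\n",
              x$k, x$n_items, x$n))
  cat(sprintf("  class probabilities: %s\n",
              paste(sprintf("%.3f", x$pi), collapse = ", ")))
  cat(sprintf("  loglik %.2f, BIC %.2f, entropy %.3f\n",
              x$loglik, x$bic, x$entropy))
  invisible(x)
}

#' @export
tidy.lca_fit <- function(x, ...) {
  as_tibble(as.data.frame(x$rho)) %>%
    mutate(class = seq_len(x$k), class_prob = x$pi) %>%
    tidyr::pivot_longer(-c("class", "class_prob"), names_to = "condition",
                        values_to = "endorsement")
}

#' @export
glance.lca_fit <- function(x, ...) {
  tibble(
    k = x$k, loglik = x$loglik, aic = x$aic, bic = x$bic, abic = x$abic,
    entropy = x$entropy, min_share = min(x$class_shares),
    converged = x$converged
  )
}

#' Plot class-conditional endorsement profiles
#'
#' Endorsement probability of each condition by latent class, as a grouped
#' bar chart — the standard display for inspecting what each comorbidity
#' class is made of.
#'
#' @param object An `lca_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lca_fit <- function(object, ...) {
  td <- tidy(object) %>%
    mutate(class = sprintf("class %d (%.1f%%)", .data$class,
                           100 * .data$class_prob))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$condition, y = .data$endorsement,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "endorsement probability", fill = NULL) +
    ggplot2::theme_minimal()
}
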