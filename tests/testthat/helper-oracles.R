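# Independent oracles used across the suite. Each re-derives a quantity by
# the most literal route available (loops, enumeration, generic
# optimization) so the vectorized implementations are checked against
# something that shares no code with them.

# Literal step-by-step entropy-weight computation: proportions, entropy,
# redundancy, weights, all with explicit loops.
oracle_entropy_weights <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z); m <- ncol(z)
  p <- matrix(0, n, m)
  for (j in 1:m) {
    cs <- sum(z[, j])
    for (i in 1:n) p[i, j] <- if (cs > 0) z[i, j] / cs else 0
  }
  e <- numeric(m)
  for (j in 1:m) {
    acc <- 0
    for (i in 1:n) if (p[i, j] > 0) acc <- acc + p[i, j] * log(p[i, j])
    e[j] <- -acc / log(n)
    if (sum(z[, j]) == 0) e[j] <- 1
  }
  d <- 1 - e
  d / sum(d)
}

# Logistic log-likelihood maximized by generic Newton iteration on the
# expanded design matrix (no IRLS, no glm).
oracle_logistic_newton <- function(x, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(x))
  for (it in 1:max_iter) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(t(x) %*% (y - mu))
    hess <- t(x) %*% (x * (mu * (1 - mu)))
    step <- solve(hess, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  beta
}

# Shapley value by the permutation-average definition: for every ordering
# of the players, each player's marginal contribution when it joins the
# coalition of its predecessors; averaged over all p! orderings.
oracle_shapley_permutations <- function(value_of_set, p) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  phi <- numeric(p)
  all_orders <- perms(seq_len(p))
  for (ord in all_orders) {
    sofar <- integer(0)
    for (j in ord) {
      phi[j] <- phi[j] + value_of_set(sort(c(sofar, j))) - value_of_set(sofar)
      sofar <- c(sofar, j)
    }
  }
  phi / length(all_orders)
}

# Saturated multinomial log-likelihood of a binary item table.
oracle_saturated_loglik <- function(y) {
  pat <- apply(y, 1, paste, collapse = "")
  counts <- table(pat)
  sum(counts * log(counts / nrow(y)))
}

# Balanced two-class panel with known polynomial curves, for trajectory
# recovery tests at arbitrary size.
make_two_class_panel <- function(n, times = 0:4,
                                 beta1 = c(0.806, -0.023),
                                 beta2 = c(0.896, 0.816, -0.118),
                                 share2 = 0.0856, sd = 0.2, seed = 1) {
  set.seed(seed)
  cls <- 1L + rbinom(n, 1L, share2)
  mu <- sapply(times, function(t) {
    ifelse(cls == 1L, sum(beta1 * t^(seq_along(beta1) - 1)),
           sum(beta2 * t^(seq_along(beta2) - 1)))
  })
  y <- mu + matrix(rnorm(n * length(times), sd = sd), n)
  tibble::tibble(
    id = rep(seq_len(n), times = length(times)),
    time = rep(times, each = n),
    score = as.vector(y),
    true_class = rep(cls, times = length(times))
  )
}
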