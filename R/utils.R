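# Internal helpers shared across modules.

# log-sum-exp over rows of a matrix, numerically stable
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# posterior matrix from per-class log joint (rows = units, cols = classes)
posterior_from_logjoint <- function(lj) {
  lse <- row_logsumexp(lj)
  exp(lj - lse)
}

# relative-entropy classification index: 1 - sum(-p log p) / (n log K).
# K = 1 is defined as 1 (a single class is perfectly "classified").
relative_entropy <- function(posterior) {
  k <- ncol(posterior)
  if (k == 1L) return(1)
  p <- pmin(pmax(posterior, 1e-300), 1)
  h <- -sum(posterior * log(p))
  1 - h / (nrow(posterior) * log(k))
}

# information criteria shared by the mixture fitters; n = number of subjects
information_criteria <- function(loglik, q, n) {
  list(
    aic  = -2 * loglik + 2 * q,
    bic  = -2 * loglik + q * log(n),
    abic = -2 * loglik + q * log((n + 2) / 24)
  )
}

# draw one integer sub-seed (< 2^31) per task from a parent seed;
# resets the RNG, so call before (not inside) any seeded sampling block
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "phbtraj_config_error")
}
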