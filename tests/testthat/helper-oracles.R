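# Independent oracles used across the suite.

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- replace(numeric(length(x)), j, eps)
    (f(x + e) - f(x - e)) / (2 * eps)
  }, 0)
}

# Finite differences of a vector-valued gradient function, column j =
# d grad / d x_j.
fd_jacobian <- function(gfun, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- replace(numeric(length(x)), j, eps)
    (gfun(x + e) - gfun(x - e)) / (2 * eps)
  }, numeric(length(gfun(x))))
}

# O(n^2) all-pairs AUC: concordant pairs count 1, ties 1/2.
auc_all_pairs <- function(pos, neg) {
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Random ordinal instance with parameters near the generator's truth, so all
# category probabilities stay comfortably positive.
random_ordinal_instance <- function(n = 40, K = 4, m = 3) {
  X <- cbind(matrix(rnorm(n * (m - 1)), n), rbinom(n, 1, 0.5))
  alpha <- sort(rnorm(K - 1, c(-1, 0, 1)[seq_len(K - 1)], 0.3))
  beta <- rnorm(m, 0, 0.6)
  params <- ordinal_params(alpha, beta)
  P <- ordinal_cumulative_probs(params, X)
  u <- runif(n)
  y <- 1L + rowSums(u > P)
  y[1:K] <- 1:K # guarantee all categories present
  list(params = params, data = grid_dataset(y, X, K = K))
}

random_multinomial_instance <- function(n = 40, K = 4, m = 3) {
  X <- cbind(matrix(rnorm(n * (m - 1)), n), rbinom(n, 1, 0.5))
  alpha <- rnorm(K - 1, 0, 0.8)
  beta <- matrix(rnorm(m * (K - 1), 0, 0.6), m)
  params <- stacked_params(alpha, beta)
  P <- multinomial_probs(params, X)
  u <- runif(n)
  y <- 1L + rowSums(u > t(apply(P, 1, cumsum))[, -K, drop = FALSE])
  y[1:K] <- 1:K
  list(params = params, data = grid_dataset(y, X, K = K))
}
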