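# Exact log-likelihood, gradient and Hessian for the three likelihoods:
#   ordinal      l_O(theta) — proportional odds (shared slopes)
#   gol          l_G(psi)   — generalized ordered logit (split-specific slopes)
#   multinomial  l_M(psi)   — baseline-category logit (reference = K)
# All three decompose over observations, which is what makes the grid
# (federated) Newton iteration exact.

# Linear predictors are clipped at +/-700 before exponentiation; exp()
# overflows just above 709 and the clip is invisible at double precision.
CLIP <- 700

clip_eta <- function(eta) {
  eta[eta > CLIP] <- CLIP
  eta[eta < -CLIP] <- -CLIP
  eta
}

# Error condition raised when a category probability is not strictly
# positive; carries the first offending row so callers can report or
# step-halve.
nonfinite_likelihood <- function(row, what = "category probability") {
  stop(structure(
    class = c("gridlogit_nonfinite", "error", "condition"),
    list(
      message = sprintf(
        "non-finite log-likelihood: nonpositive %s at row %d", what, row
      ),
      call = sys.call(-1), row = row
    )
  ))
}

#' Cumulative response probabilities under the proportional-odds model
#'
#' Computes `Pr(Y <= w | x_i) = plogis(alpha_w + beta' x_i)` for every
#' observation and every split `w = 1..K-1`.
#'
#' @param params An [ordinal_params()] object.
#' @param X Numeric covariate matrix (`n x m`).
#' @return Numeric matrix `n x (K-1)` of cumulative probabilities.
#' @examples
#' ordinal_cumulative_probs(ordinal_params(c(-1, 1), 0), matrix(2.5))
#' @export
ordinal_cumulative_probs <- function(params, X) {
  stopifnot(inherits(params, "ordinal_params"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = length(params$beta))
  if (ncol(X) != params$m) {
    stop("ordinal_cumulative_probs: ncol(X) must equal length(beta)")
  }
  xb <- drop(X %*% params$beta)
  eta <- clip_eta(outer(xb, params$alpha, `+`))
  stats::plogis(eta)
}

# Shared machinery for the two cumulative-difference likelihoods. Takes the
# n x (K-1) cumulative probability matrix and returns per-observation category
# probabilities pi_i = P[w_i] - P[w_i - 1] (with P[0] = 0, P[K] = 1) plus the
# boundary derivative weights used by gradient and Hessian.
cumulative_pieces <- function(P, y, K) {
  n <- length(y)
  Pfull <- cbind(0, P, 1)
  idx_up <- cbind(seq_len(n), y + 1L)
  idx_lo <- cbind(seq_len(n), y)
  pii <- Pfull[idx_up] - Pfull[idx_lo]
  if (any(!is.finite(pii)) || any(pii <= 0)) {
    nonfinite_likelihood(which(!is.finite(pii) | pii <= 0)[1L])
  }
  g <- P * (1 - P) # d sigma / d eta
  h <- g * (1 - 2 * P) # d^2 sigma / d eta^2
  # S[i, v] = I[v == y_i] - I[v == y_i - 1]: which splits bound category y_i
  S <- matrix(0, n, K - 1L)
  up <- y <= K - 1L
  S[cbind(which(up), y[up])] <- 1
  lo <- y >= 2L
  S[cbind(which(lo), y[lo] - 1L)] <- -1
  list(pii = pii, A = g * S, Th = h * S)
}

#' Log-likelihood, gradient and Hessian of the proportional-odds model
#'
#' Analytic derivatives of `l_O(theta)` with respect to the flattened
#' parameter vector `(alpha_1..alpha_{K-1}, beta_1..beta_m)`.
#'
#' @param params An [ordinal_params()] object.
#' @param data A [grid_dataset()].
#' @return A list of class `model_derivatives` with elements `loglik`
#'   (scalar), `gradient` (length `K-1+m`) and `hessian`
#'   (`(K-1+m) x (K-1+m)`, symmetric).
#' @export
ordinal_derivatives <- function(params, data) {
  stopifnot(inherits(params, "ordinal_params"), inherits(data, "grid_dataset"))
  if (params$m != data$m || params$K != data$K) {
    stop("ordinal_derivatives: parameter dimensions do not match data")
  }
  K <- data$K
  y <- data$y
  X <- data$X
  P <- ordinal_cumulative_probs(params, X)
  pc <- cumulative_pieces(P, y, K)
  pii <- pc$pii
  A <- pc$A # n x (K-1): d pi_i / d alpha_v
  Th <- pc$Th # n x (K-1): second-derivative boundary weights
  cvec <- rowSums(A) # d pi_i / d beta = cvec_i * x_i

  loglik <- sum(log(pii))
  grad <- c(colSums(A / pii), drop(crossprod(X, cvec / pii)))

  A2 <- A / pii
  B2 <- X * (cvec / pii)
  Tp <- Th / pii
  Haa <- diag(colSums(Tp), K - 1L) - crossprod(A2)
  Hab <- crossprod(Tp, X) - crossprod(A2, B2)
  Hbb <- crossprod(X, X * (rowSums(Th) / pii)) - crossprod(B2)
  H <- rbind(cbind(Haa, Hab), cbind(t(Hab), Hbb))
  model_derivatives(loglik, grad, H)
}

#' Log-likelihood, gradient and Hessian of the generalized ordered logit
#'
#' The generalized ordered logit replaces the shared slope vector of the
#' proportional-odds model with a split-specific `beta_w` per cumulative
#' split; it is the alternative hypothesis of the proportional-odds score
#' test. Category probabilities are cumulative differences and are not
#' guaranteed positive away from the null, so this likelihood can fail with a
#' non-finite-likelihood error at valid-looking parameter values.
#'
#' @param params A [stacked_params()] object.
#' @param data A [grid_dataset()].
#' @return A `model_derivatives` list; gradient and Hessian follow the
#'   block-major flattening `(alpha_1, beta_1', ..., alpha_{K-1}, beta_{K-1}')`.
#' @export
gol_derivatives <- function(params, data) {
  stopifnot(inherits(params, "stacked_params"), inherits(data, "grid_dataset"))
  if (params$m != data$m || params$K != data$K) {
    stop("gol_derivatives: parameter dimensions do not match data")
  }
  K <- data$K
  m <- data$m
  n <- data$n
  y <- data$y
  Z <- cbind(1, data$X) # block design: eta_w = z' (alpha_w, beta_w)
  eta <- clip_eta(Z %*% rbind(params$alpha, params$beta))
  P <- stats::plogis(eta)
  pc <- cumulative_pieces(P, y, K)
  pii <- pc$pii
  A <- pc$A
  Th <- pc$Th

  loglik <- sum(log(pii))
  p1 <- m + 1L
  npar <- (K - 1L) * p1
  grad <- as.numeric(crossprod(Z, A / pii))
  H <- matrix(0, npar, npar)
  for (v in seq_len(K - 1L)) {
    for (vp in v:(K - 1L)) {
      wgt <- -A[, v] * A[, vp] / pii^2
      if (vp == v) wgt <- wgt + Th[, v] / pii
      blk <- crossprod(Z, Z * wgt)
      ri <- (v - 1L) * p1 + seq_len(p1)
      ci <- (vp - 1L) * p1 + seq_len(p1)
      H[ri, ci] <- blk
      if (vp != v) H[ci, ri] <- t(blk)
    }
  }
  model_derivatives(loglik, grad, H)
}

#' Class probabilities under the multinomial (baseline-category) logit
#'
#' `Pr(Y = w | x_i)` for `w < K` is `exp(alpha_w + beta_w' x_i)` normalized
#' against all categories, with category `K` as the reference (`eta_K = 0`).
#' Computed with log-sum-exp stabilization.
#'
#' @param params A [stacked_params()] object.
#' @param X Numeric covariate matrix (`n x m`).
#' @return Numeric matrix `n x K`; every row sums to 1.
#' @examples
#' p <- multinomial_probs(
#'   stacked_params(c(2, 3, 1), matrix(c(.5, .5, .5, .5, 2, 2, 2, 2, 1, 1, 1, 1), 4)),
#'   matrix(0, 1, 4)
#' )
#' rowSums(p)
#' @export
multinomial_probs <- function(params, X) {
  stopifnot(inherits(params, "stacked_params"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = params$m)
  if (ncol(X) != params$m) {
    stop("multinomial_probs: ncol(X) must equal nrow(beta)")
  }
  eta <- cbind(clip_eta(cbind(1, X) %*% rbind(params$alpha, params$beta)), 0)
  # subtract the row maximum before exponentiating (log-sum-exp)
  a <- eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
  ex <- exp(eta - a)
  ex / rowSums(ex)
}

#' Log-likelihood, gradient and Hessian of the multinomial logit
#'
#' Analytic derivatives of `l_M(psi)` under the block-major flattening.
#' The Hessian is negative semidefinite everywhere, so no step-halving
#' safeguards are needed for this likelihood.
#'
#' @param params A [stacked_params()] object.
#' @param data A [grid_dataset()].
#' @return A `model_derivatives` list.
#' @export
multinomial_derivatives <- function(params, data) {
  stopifnot(inherits(params, "stacked_params"), inherits(data, "grid_dataset"))
  if (params$m != data$m || params$K != data$K) {
    stop("multinomial_derivatives: parameter dimensions do not match data")
  }
  K <- data$K
  m <- data$m
  n <- data$n
  y <- data$y
  Z <- cbind(1, data$X)
  eta <- cbind(clip_eta(Z %*% rbind(params$alpha, params$beta)), 0)
  a <- apply(eta, 1L, max)
  lse <- a + log(rowSums(exp(eta - a)))
  P <- exp(eta - lse) # n x K
  loglik <- sum(eta[cbind(seq_len(n), y)] - lse)

  Yind <- matrix(0, n, K - 1L)
  lt <- y <= K - 1L
  Yind[cbind(which(lt), y[lt])] <- 1
  grad <- as.numeric(crossprod(Z, Yind - P[, seq_len(K - 1L), drop = FALSE]))

  p1 <- m + 1L
  npar <- (K - 1L) * p1
  H <- matrix(0, npar, npar)
  for (v in seq_len(K - 1L)) {
    for (vp in v:(K - 1L)) {
      wgt <- -P[, v] * ((vp == v) - P[, vp])
      blk <- crossprod(Z, Z * wgt)
      ri <- (v - 1L) * p1 + seq_len(p1)
      ci <- (vp - 1L) * p1 + seq_len(p1)
      H[ri, ci] <- blk
      if (vp != v) H[ci, ri] <- t(blk)
    }
  }
  model_derivatives(loglik, grad, H)
}

model_derivatives <- function(loglik, gradient, hessian) {
  structure(
    list(loglik = loglik, gradient = gradient, hessian = hessian),
    class = "model_derivatives"
  )
}

#' @export
print.model_derivatives <- function(x, ...) {
  cat(sprintf(
    "<model_derivatives> loglik = %.6f, %d parameters\n",
    x$loglik, length(x$gradient)
  ))
  invisible(x)
}

# Single dispatch point used by the grid engine: model is one of
# "ordinal", "gol", "multinomial"; params is the flattened vector.
model_eval <- function(model, params, data) {
  switch(model,
    ordinal = ordinal_derivatives(
      unflatten_ordinal(params, data$K, data$m), data
    ),
    gol = gol_derivatives(
      unflatten_stacked(params, data$K, data$m), data
    ),
    multinomial = multinomial_derivatives(
      unflatten_stacked(params, data$K, data$m), data
    ),
    stop("unknown model identifier: ", model)
  )
}

n_params <- function(model, K, m) {
  switch(model,
    ordinal = (K - 1L) + m,
    gol = ,
    multinomial = (K - 1L) * (m + 1L),
    stop("unknown model identifier: ", model)
  )
}
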