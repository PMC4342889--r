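#' Proportional-odds parameter vector
#'
#' The proportional-odds (cumulative logit) model uses one cut-point intercept
#' per cumulative split and a single slope vector shared across splits:
#' \deqn{\mathrm{logit}\, \Pr(Y \le w \mid x) = \alpha_w + \beta^T x,
#'   \quad w = 1, \dots, K-1.}
#' The flattened parameter order is `(alpha_1..alpha_{K-1}, beta_1..beta_m)`.
#'
#' Note the sign convention: the linear predictor is `alpha_w + beta' x`.
#' Many reference implementations (e.g. `MASS::polr`) parameterize
#' `zeta_w - beta' x`, so their slopes are the negation of these.
#'
#' @param alpha Numeric vector of `K - 1` cut-point intercepts.
#' @param beta Numeric vector of `m` shared slopes.
#' @return An object of class `ordinal_params`.
#' @examples
#' ordinal_params(alpha = c(-1, 0, 1), beta = rep(1, 4))
#' @export
ordinal_params <- function(alpha, beta) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  if (length(alpha) < 2L) stop("ordinal_params: need K - 1 >= 2 intercepts")
  if (length(beta) < 1L) stop("ordinal_params: need at least one slope")
  structure(
    list(alpha = alpha, beta = beta, K = length(alpha) + 1L, m = length(beta)),
    class = "ordinal_params"
  )
}

#' Block-stacked parameter vector
#'
#' Shared by the generalized ordered logit and the multinomial model: one
#' `(alpha_w, beta_w)` block per non-reference split/category, flattened
#' block-major as `(alpha_1, beta_1', ..., alpha_{K-1}, beta_{K-1}')`,
#' total length `(K-1)(m+1)`.
#'
#' @param alpha Numeric vector of `K - 1` intercepts.
#' @param beta Numeric matrix `m x (K-1)`; column `w` is the slope vector of
#'   block `w`. A list of `K - 1` slope vectors is also accepted.
#' @return An object of class `stacked_params`.
#' @examples
#' stacked_params(alpha = c(2, 3, 1), beta = cbind(rep(0.5, 4), rep(2, 4), rep(1, 4)))
#' @export
stacked_params <- function(alpha, beta) {
  alpha <- as.numeric(alpha)
  if (is.list(beta)) beta <- do.call(cbind, beta)
  beta <- as.matrix(beta)
  if (ncol(beta) != length(alpha)) {
    stop("stacked_params: need one slope column per intercept")
  }
  structure(
    list(
      alpha = alpha, beta = beta,
      K = length(alpha) + 1L, m = nrow(beta)
    ),
    class = "stacked_params"
  )
}

#' @export
print.ordinal_params <- function(x, ...) {
  cat("<ordinal_params> K =", x$K, " m =", x$m, "\n")
  cat("alpha:", format(x$alpha, digits = 4), "\n")
  cat("beta: ", format(x$beta, digits = 4), "\n")
  invisible(x)
}

#' @export
print.stacked_params <- function(x, ...) {
  cat("<stacked_params> K =", x$K, " m =", x$m, "\n")
  for (w in seq_along(x$alpha)) {
    cat(sprintf(
      "block %d: alpha = %s  beta = (%s)\n", w,
      format(x$alpha[w], digits = 4),
      paste(format(x$beta[, w], digits = 4), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Flatten a parameter object to a bare numeric vector
#'
#' @param params An `ordinal_params` or `stacked_params` object (bare numeric
#'   vectors pass through unchanged).
#' @return Numeric vector in the model's canonical flattening order.
#' @export
flatten_params <- function(params) {
  if (is.numeric(params)) {
    return(as.numeric(params))
  }
  if (inherits(params, "ordinal_params")) {
    return(c(params$alpha, params$beta))
  }
  if (inherits(params, "stacked_params")) {
    return(as.numeric(rbind(params$alpha, params$beta)))
  }
  stop("flatten_params: unsupported parameter object")
}

# Inverse of flatten_params for each model family; K and m fix the shape.
unflatten_ordinal <- function(theta, K, m) {
  stopifnot(length(theta) == (K - 1L) + m)
  ordinal_params(alpha = theta[seq_len(K - 1L)], beta = theta[K:(K - 1L + m)])
}

unflatten_stacked <- function(psi, K, m) {
  stopifnot(length(psi) == (K - 1L) * (m + 1L))
  blocks <- matrix(psi, nrow = m + 1L, ncol = K - 1L)
  stacked_params(alpha = blocks[1L, ], beta = blocks[-1L, , drop = FALSE])
}

#' Embed a proportional-odds fit in the generalized ordered logit space
#'
#' Maps `theta = (alpha, beta)` to the stacked vector whose every block
#' carries the same shared slope: `(alpha_1, beta', ..., alpha_{K-1}, beta')`.
#' This is the restricted point at which the proportional-odds score test
#' evaluates the generalized model's gradient and information.
#'
#' @param params An [ordinal_params()] object or a flattened ordinal vector
#'   (in which case `K` and `m` must be supplied).
#' @param K,m Dimensions, required only for bare numeric input.
#' @return A [stacked_params()] object.
#' @examples
#' embed_ordinal_in_gol(ordinal_params(c(-1, 0, 1), rep(1, 4)))
#' @export
embed_ordinal_in_gol <- function(params, K = NULL, m = NULL) {
  if (is.numeric(params)) {
    if (is.null(K) || is.null(m)) {
      stop("embed_ordinal_in_gol: supply K and m with a bare numeric vector")
    }
    params <- unflatten_ordinal(params, K, m)
  }
  stopifnot(inherits(params, "ordinal_params"))
  stacked_params(
    alpha = params$alpha,
    beta = matrix(params$beta, nrow = params$m, ncol = params$K - 1L)
  )
}
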