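#' Predicted probabilities from a grid fit
#'
#' @param object A [grid_newton()] fit.
#' @param newdata Covariate matrix (`n x m`).
#' @param type `"class_probs"` returns the `n x K` class probability matrix
#'   for any model; `"cumulative"` returns the `n x (K-1)` cumulative
#'   probability matrix (ordinal and generalized ordered logit only).
#' @param ... Unused.
#' @return A probability matrix.
#' @export
predict.grid_fit <- function(object, newdata,
                             type = c("class_probs", "cumulative"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = object$m)
  K <- object$K
  theta <- unname(object$params)
  if (object$model == "ordinal") {
    P <- ordinal_cumulative_probs(unflatten_ordinal(theta, K, object$m), newdata)
  } else if (object$model == "gol") {
    sp <- unflatten_stacked(theta, K, object$m)
    P <- stats::plogis(clip_eta(
      cbind(1, newdata) %*% rbind(sp$alpha, sp$beta)
    ))
  } else {
    if (type == "cumulative") {
      stop("predict.grid_fit: cumulative probabilities are undefined for the multinomial model")
    }
    return(multinomial_probs(
      unflatten_stacked(theta, K, object$m), newdata
    ))
  }
  if (type == "cumulative") {
    return(P)
  }
  cbind(P, 1)[, seq_len(K), drop = FALSE] -
    cbind(0, P)[, seq_len(K), drop = FALSE]
}
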