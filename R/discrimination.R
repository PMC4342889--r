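# Classification performance measures computable from pooled (label, score)
# pairs: rank-sum binary AUC, pairwise class AUCs, the Hand-Till generalized
# AUC for multinomial fits, and the mean cumulative-split AUC for ordinal
# fits. All are functions of ranks only, so pooling predictions from several
# sites and then computing equals computing on pooled data.

#' Rank-sum (Mann-Whitney) binary AUC
#'
#' `A(1|0) = (R - n1 (n1 + 1) / 2) / (n1 n2)` where `R` is the sum of
#' mid-ranks of the positive-class scores among all scores. Equals the
#' fraction of (positive, negative) pairs in which the positive score is
#' higher, counting ties as 1/2.
#'
#' @param pos_scores Scores of positive-class observations.
#' @param neg_scores Scores of negative-class observations.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_binary(c(0.9, 0.8), c(0.3, 0.1))
#' @export
auc_binary <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  if (n1 < 1L || n2 < 1L) {
    stop("auc_binary: both classes need at least one observation")
  }
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  R <- sum(r[seq_len(n1)])
  (R - (n1 + 1) * n1 / 2) / (n1 * n2)
}

#' Pairwise class AUC
#'
#' `A(k1|k2)`: the binary AUC restricted to observations labeled `k1` or
#' `k2`, with `k1` as the positive class and the estimated `Pr(Y = k1)` as
#' the score. Note `A(k1|k2)` and `A(k2|k1)` use different score columns and
#' need not sum to 1.
#'
#' @param labels Integer class labels.
#' @param scores Estimated `Pr(Y = k1)` per observation.
#' @param k1 Positive class.
#' @param k2 Negative class.
#' @return AUC in `[0, 1]`.
#' @export
auc_pairwise <- function(labels, scores, k1, k2) {
  if (length(labels) != length(scores)) stop("auc_pairwise: length mismatch")
  pos <- scores[labels == k1]
  neg <- scores[labels == k2]
  if (!length(pos) || !length(neg)) {
    stop("auc_pairwise: class ", if (!length(pos)) k1 else k2, " is empty")
  }
  auc_binary(pos, neg)
}

#' Hand-Till generalized AUC for multi-class fits
#'
#' The mean over all unordered class pairs of the symmetrized pairwise
#' separability `[A(k1|k2) + A(k2|k1)] / 2`, where `A(k1|k2)` scores class
#' `k1` against `k2` using the estimated `Pr(Y = k1)`.
#'
#' @param labels Integer class labels `1..K`; every class must be present.
#' @param probs `n x K` matrix of estimated class probabilities.
#' @return Generalized AUC in `[0, 1]`.
#' @export
auc_hand_till <- function(labels, probs) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  if (nrow(probs) != length(labels)) stop("auc_hand_till: dimension mismatch")
  present <- seq_len(K) %in% labels
  if (!all(present)) {
    stop("auc_hand_till: class ", which(!present)[1L], " has no observations")
  }
  total <- 0
  for (k1 in seq_len(K - 1L)) {
    for (k2 in (k1 + 1L):K) {
      a12 <- auc_pairwise(labels, probs[, k1], k1, k2)
      a21 <- auc_pairwise(labels, probs[, k2], k2, k1)
      total <- total + (a12 + a21) / 2
    }
  }
  total / (K * (K - 1) / 2)
}

#' Mean cumulative-split AUC for ordinal fits
#'
#' The mean over `w = 1..K-1` of the binary AUC for the collapse
#' `[Y <= w]` versus `[Y > w]`, scored by the fitted `Pr(Y <= w)`.
#'
#' @param labels Integer outcome `1..K`.
#' @param cumprobs `n x (K-1)` matrix of fitted cumulative probabilities.
#' @return Mean AUC in `[0, 1]`.
#' @export
auc_ordinal_mean <- function(labels, cumprobs) {
  cumprobs <- as.matrix(cumprobs)
  if (nrow(cumprobs) != length(labels)) {
    stop("auc_ordinal_mean: dimension mismatch")
  }
  Km1 <- ncol(cumprobs)
  aucs <- vapply(seq_len(Km1), function(w) {
    le <- labels <= w
    if (!any(le) || all(le)) {
      stop("auc_ordinal_mean: collapse Y<=", w, " has an empty side")
    }
    auc_binary(cumprobs[le, w], cumprobs[!le, w])
  }, 0)
  mean(aucs)
}

#' Cross-validated grid AUC
#'
#' Ten-fold (by default) cross-validation of the grid fit's discrimination:
#' each site's rows are dealt into folds stratified by outcome class, the
#' model is grid-fitted with fold `f` held out everywhere, held-out
#' predictions are pooled across folds and sites, and a single AUC is
#' computed from the pooled pairs (mean cumulative-split AUC for ordinal
#' models, Hand-Till for multinomial).
#'
#' @param model `"ordinal"` or `"multinomial"`.
#' @param sites List of [grid_dataset()] sites.
#' @param folds Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#' @param config A [newton_config()].
#' @return The cross-validated AUC (scalar).
#' @export
cv_auc <- function(model, sites, folds = 10L, seed = 1L,
                   config = newton_config()) {
  if (inherits(sites, "grid_dataset")) sites <- list(sites)
  K <- sites[[1L]]$K
  set.seed(seed)
  # per site: fold id per row, stratified by class so folds keep all classes
  fold_ids <- lapply(sites, function(d) {
    f <- integer(d$n)
    for (k in seq_len(K)) {
      rows <- which(d$y == k)
      f[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    f
  })
  labels <- integer(0)
  preds <- NULL
  for (f in seq_len(folds)) {
    train <- lapply(seq_along(sites), function(u) {
      keep <- fold_ids[[u]] != f
      grid_dataset(sites[[u]]$y[keep],
        sites[[u]]$X[keep, , drop = FALSE],
        K = K
      )
    })
    fit <- grid_newton(model, train, config = config)
    for (u in seq_along(sites)) {
      hold <- fold_ids[[u]] == f
      if (!any(hold)) next
      Xh <- sites[[u]]$X[hold, , drop = FALSE]
      p <- if (model == "ordinal") {
        ordinal_cumulative_probs(
          unflatten_ordinal(unname(fit$params), K, fit$m), Xh
        )
      } else {
        multinomial_probs(
          unflatten_stacked(unname(fit$params), K, fit$m), Xh
        )
      }
      labels <- c(labels, sites[[u]]$y[hold])
      preds <- rbind(preds, p)
    }
  }
  if (model == "ordinal") {
    auc_ordinal_mean(labels, preds)
  } else {
    auc_hand_till(labels, preds)
  }
}
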