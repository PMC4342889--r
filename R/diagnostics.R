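# Model-checking machinery: the grid score test of the proportional-odds
# assumption against the generalized ordered logit, and Hosmer-Lemeshow-type
# goodness-of-fit tests (binary, extended/multinomial, and the per-collapse
# battery for ordinal fits).

#' Grid score test of the proportional-odds assumption
#'
#' Tests `beta_1 = ... = beta_{K-1}` by evaluating the generalized ordered
#' logit gradient and observed information at the restricted point
#' `psi~ = (alpha^_1, beta^, ..., alpha^_{K-1}, beta^)` built from the
#' proportional-odds MLE. The statistic is the score quadratic form
#' `g' [-H]^{-1} g`, aggregated over sites exactly like the fit itself; it is
#' asymptotically chi-squared with `m (K - 2)` degrees of freedom under the
#' null. No refit of the larger model is needed.
#'
#' @param fit A converged ordinal [grid_newton()] fit.
#' @param sites The list of [grid_dataset()] sites the fit used.
#' @return A list of class `grid_score_test`: `statistic`, `df`, `pvalue`.
#' @examples
#' sites <- split_dataset(gen_ordinal(600, seed = 1), c(200, 400))
#' fit <- grid_newton("ordinal", sites)
#' score_test_po(fit, sites)
#' @export
score_test_po <- function(fit, sites) {
  stopifnot(inherits(fit, "grid_fit"))
  if (fit$model != "ordinal") {
    stop("score_test_po: fit must be a proportional-odds ('ordinal') fit")
  }
  if (!fit$converged) stop("score_test_po: fit did not converge")
  if (inherits(sites, "grid_dataset")) sites <- list(sites)
  psi <- flatten_params(
    embed_ordinal_in_gol(unflatten_ordinal(unname(fit$params), fit$K, fit$m))
  )
  agg <- aggregate_summaries(lapply(seq_along(sites), function(u) {
    site_summary("gol", psi, sites[[u]], site_id = u)
  }))
  info <- -agg$hessian
  stat <- tryCatch(
    drop(crossprod(agg$gradient, solve(info, agg$gradient))),
    error = function(e) {
      stop("score_test_po: aggregated information matrix is singular")
    }
  )
  if (stat < -1e-10) {
    stop("score_test_po: negative quadratic form; information not positive definite")
  }
  stat <- max(stat, 0)
  df <- fit$m * (fit$K - 2L)
  structure(
    list(
      statistic = stat, df = df,
      pvalue = stats::pchisq(stat, df, lower.tail = FALSE)
    ),
    class = "grid_score_test"
  )
}

#' @export
print.grid_score_test <- function(x, ...) {
  cat(sprintf(
    "Proportional-odds score test: T = %.4f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$pvalue
  ))
  invisible(x)
}

# Equal-count bin assignment for n sorted observations into g groups: the
# first (n mod g) bins take one extra observation, so sizes differ by at
# most 1.
hl_bins <- function(n, g) {
  sizes <- rep(n %/% g, g) + (seq_len(g) <= n %% g)
  rep.int(seq_len(g), sizes)
}

#' Hosmer-Lemeshow test for binary outcomes
#'
#' Observations are sorted by predicted probability (stably, so ties keep
#' input order) and split into `g` near-equal-size groups. The statistic
#' compares observed and expected counts of both outcome classes in each
#' group and is asymptotically chi-squared with `g - 2` degrees of freedom.
#'
#' @param y01 Binary outcome vector (0/1).
#' @param phat Predicted probabilities of `y = 1`, strictly inside (0, 1).
#' @param g Number of groups (default 10, the classical deciles-of-risk).
#' @return A list of class `grid_hl`: `statistic`, `df`, `pvalue`, `g`, and
#'   `table`, a data frame of per-group observed (`O0`, `O1`) and expected
#'   (`E0`, `E1`) counts.
#' @export
hl_binary <- function(y01, phat, g = 10L) {
  y01 <- as.numeric(y01)
  if (!all(y01 %in% c(0, 1))) stop("hl_binary: y01 must be 0/1")
  if (length(y01) != length(phat)) stop("hl_binary: length mismatch")
  if (any(phat <= 0 | phat >= 1)) {
    stop("hl_binary: predicted probabilities must be strictly inside (0,1)")
  }
  n <- length(y01)
  if (n < g) stop("hl_binary: need at least g observations")
  ord <- order(phat) # radix sort: stable, ties keep input order
  bin <- hl_bins(n, g)
  size <- tabulate(bin, nbins = g)
  O1 <- as.numeric(rowsum(y01[ord], bin))
  E1 <- as.numeric(rowsum(phat[ord], bin))
  O0 <- size - O1
  E0 <- size - E1
  if (any(c(E0, E1) == 0)) {
    stop(
      "hl_binary: zero expected count in group ",
      which(E0 == 0 | E1 == 0)[1L]
    )
  }
  stat <- sum((O1 - E1)^2 / E1) + sum((O0 - E0)^2 / E0)
  df <- g - 2L
  structure(
    list(
      statistic = stat, df = df,
      pvalue = stats::pchisq(stat, df, lower.tail = FALSE), g = g,
      table = data.frame(group = seq_len(g), n = size, O0 = O0, E0 = E0,
        O1 = O1, E1 = E1)
    ),
    class = "grid_hl"
  )
}

#' Extended Hosmer-Lemeshow test for K-category outcomes
#'
#' Observations are sorted by the predicted probability of `Y < K` (one minus
#' the reference-category probability), split into `g` near-equal groups, and
#' observed versus expected counts are compared across all `K` classes. The
#' statistic is asymptotically chi-squared with `(g - 2)(K - 1)` degrees of
#' freedom.
#'
#' @param y Outcome vector coded `1..K`.
#' @param probs `n x K` matrix of predicted class probabilities; rows must
#'   sum to 1 (tolerance `1e-8`).
#' @param g Number of groups (default 10).
#' @return A list of class `grid_hl` with a `g x K` observed/expected table.
#' @export
hl_extended <- function(y, probs, g = 10L) {
  probs <- as.matrix(probs)
  n <- length(y)
  K <- ncol(probs)
  if (nrow(probs) != n) stop("hl_extended: dimension mismatch")
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    stop("hl_extended: probability rows must sum to 1")
  }
  if (any(y < 1 | y > K)) stop("hl_extended: y out of range 1..K")
  if (n < g) stop("hl_extended: need at least g observations")
  score <- 1 - probs[, K] # Pr(Y < K)
  ord <- order(score)
  bin <- hl_bins(n, g)
  O <- matrix(0, g, K)
  cnt <- table(factor(bin, levels = seq_len(g)), factor(y[ord], levels = seq_len(K)))
  O[] <- as.numeric(cnt)
  E <- rowsum(probs[ord, , drop = FALSE], bin)
  if (any(E == 0)) {
    stop(
      "hl_extended: zero expected count in group ",
      which(rowSums(E == 0) > 0)[1L]
    )
  }
  stat <- sum((O - E)^2 / E)
  df <- (g - 2L) * (K - 1L)
  tab <- data.frame(group = seq_len(g), n = tabulate(bin, nbins = g))
  for (k in seq_len(K)) {
    tab[[paste0("O", k)]] <- O[, k]
    tab[[paste0("E", k)]] <- E[, k]
  }
  structure(
    list(
      statistic = stat, df = df,
      pvalue = stats::pchisq(stat, df, lower.tail = FALSE), g = g, table = tab
    ),
    class = "grid_hl"
  )
}

#' @export
print.grid_hl <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow test: statistic = %.4f, df = %d, p = %.4g (g = %d)\n",
    x$statistic, x$df, x$pvalue, x$g
  ))
  invisible(x)
}

#' Per-collapse Hosmer-Lemeshow battery for an ordinal fit
#'
#' Goodness of fit of a proportional-odds model is assessed by running the
#' binary Hosmer-Lemeshow test on each of the `K - 1` cumulative collapses
#' `[Y <= w]` against the fitted `Pr(Y <= w)`. The overall verdict is
#' `"all"` (every collapse nonsignificant at `level`) by default; `"any"`
#' (at least one nonsignificant) is available because the convention behind
#' a single reported rate is ambiguous.
#'
#' @param y Outcome vector coded `1..K`.
#' @param cumprobs `n x (K-1)` matrix of fitted cumulative probabilities.
#' @param g Number of groups per collapse (default 10).
#' @param level Significance level for the overall verdict (default 0.05).
#' @param rule `"all"` or `"any"`.
#' @return A list of class `grid_hl_battery`: `tests` (K-1 [hl_binary()]
#'   results), `pvalues`, `pass`, `rule`, `level`.
#' @export
ordinal_hl_battery <- function(y, cumprobs, g = 10L, level = 0.05,
                               rule = c("all", "any")) {
  rule <- match.arg(rule)
  cumprobs <- as.matrix(cumprobs)
  Km1 <- ncol(cumprobs)
  tests <- lapply(seq_len(Km1), function(w) {
    hl_binary(as.numeric(y <= w), cumprobs[, w], g = g)
  })
  pvalues <- vapply(tests, `[[`, 0, "pvalue")
  pass <- if (rule == "all") all(pvalues >= level) else any(pvalues >= level)
  structure(
    list(tests = tests, pvalues = pvalues, pass = pass, rule = rule,
      level = level),
    class = "grid_hl_battery"
  )
}

#' @export
print.grid_hl_battery <- function(x, ...) {
  cat(sprintf(
    "Ordinal HL battery (%d collapses, rule '%s' at level %.2f): %s\n",
    length(x$pvalues), x$rule, x$level, if (x$pass) "pass" else "FAIL"
  ))
  cat("p-values:", paste(sprintf("%.4f", x$pvalues), collapse = "  "), "\n")
  invisible(x)
}
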