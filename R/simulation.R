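# Synthetic multi-site study harness. The generators emulate the four study
# designs used to validate the grid method: two continuous standard-normal
# covariates, two Bernoulli(0.5) covariates, four outcome categories, and
# either a proportional-odds or a multinomial data-generating process with
# fixed coefficient vectors. Total sample sizes are 1800 (Studies 1 and 3)
# and 900 (Studies 2 and 4), each dealt to three sites in three different
# ways.

sim_covariates <- function(n) {
  X <- cbind(
    x1 = stats::rnorm(n), x2 = stats::rnorm(n),
    x3 = stats::rbinom(n, 1L, 0.5), x4 = stats::rbinom(n, 1L, 0.5)
  )
  X
}

#' Generate data from the ordinal (proportional-odds) study design
#'
#' Covariates `x1, x2 ~ N(0,1)` and `x3, x4 ~ Bernoulli(0.5)`, independent;
#' the outcome has `K = 4` categories with cumulative logits
#' `alpha_w + beta' x`, `alpha = (-1, 0, 1)` and unit slopes by default.
#'
#' @param n Number of observations.
#' @param seed Optional seed; when supplied the dataset is reproducible.
#' @param alpha Cut-point intercepts (length `K - 1`).
#' @param beta Shared slopes (length 4).
#' @return A [grid_dataset()].
#' @examples
#' gen_ordinal(10, seed = 42)
#' @export
gen_ordinal <- function(n, seed = NULL, alpha = c(-1, 0, 1), beta = rep(1, 4)) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  X <- sim_covariates(n)
  params <- ordinal_params(alpha, beta)
  P <- ordinal_cumulative_probs(params, X)
  u <- stats::runif(n)
  y <- 1L + rowSums(u > P)
  grid_dataset(y, X, K = length(alpha) + 1L)
}

#' Generate data from the multinomial study design
#'
#' Covariates as in [gen_ordinal()]; the outcome follows a baseline-category
#' logit with reference class `K = 4` and, by default, intercepts
#' `(2, 3, 1)` and slope vectors `(0.5, 0.5, 0.5, 0.5)`, `(2, 2, 2, 2)`,
#' `(1, 1, 1, 1)` for classes 1-3.
#'
#' @param n Number of observations.
#' @param seed Optional seed.
#' @param alpha Intercepts (length `K - 1`).
#' @param beta `m x (K-1)` slope matrix, one column per non-reference class.
#' @return A [grid_dataset()].
#' @examples
#' gen_multinomial(10, seed = 42)
#' @export
gen_multinomial <- function(n, seed = NULL, alpha = c(2, 3, 1),
                            beta = cbind(rep(0.5, 4), rep(2, 4), rep(1, 4))) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  X <- sim_covariates(n)
  params <- stacked_params(alpha, beta)
  P <- multinomial_probs(params, X)
  cums <- t(apply(P, 1L, cumsum))
  u <- stats::runif(n)
  y <- 1L + rowSums(u > cums[, -ncol(cums), drop = FALSE])
  grid_dataset(y, X, K = length(alpha) + 1L)
}

#' Split a dataset into consecutive-row sites
#'
#' @param data A [grid_dataset()].
#' @param sizes Integer vector of site sizes summing to `data$n`.
#' @return A list of [grid_dataset()] objects.
#' @export
split_dataset <- function(data, sizes) {
  stopifnot(inherits(data, "grid_dataset"), sum(sizes) == data$n)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(u) {
    idx <- starts[u]:ends[u]
    grid_dataset(data$y[idx], data$X[idx, , drop = FALSE], K = data$K)
  })
}

# The three site splits printed for each total sample size.
study_splits <- list(
  `1800` = list(c(600, 600, 600), c(100, 200, 1500), c(50, 50, 1700)),
  `900` = list(c(300, 300, 300), c(50, 100, 750), c(24, 26, 850))
)

#' Define one of the four simulation study designs
#'
#' Studies 1 and 2 use the proportional-odds generator at total sample sizes
#' 1800 and 900; Studies 3 and 4 use the multinomial generator at the same
#' sizes. Each replicate's pooled stream is halved - the first half fits the
#' model, the second half evaluates AUC and goodness of fit - and the fitting
#' half is dealt to three sites according to `site_split` (site `u` holds
#' `ceiling(n_u / 2)` fitting rows; for all six printed splits those sum to
#' exactly half the total). Because the grid fit depends on the pooled
#' fitting rows only, every split of a study yields identical results.
#'
#' @param study Study id, 1-4.
#' @param site_split Which of the study's three site splits to use (index
#'   1-3, or an explicit integer triple summing to the total size).
#' @param reps Number of Monte-Carlo replicates (default 1000).
#' @param seed Master seed; replicate `r` uses `seed + r`.
#' @return A list of class `study_design`.
#' @export
study_design <- function(study, site_split = 1L, reps = 1000L, seed = 20150218L) {
  stopifnot(study %in% 1:4)
  n_total <- if (study %in% c(1L, 3L)) 1800L else 900L
  model <- if (study <= 2L) "ordinal" else "multinomial"
  if (length(site_split) == 1L) {
    site_split <- study_splits[[as.character(n_total)]][[site_split]]
  }
  stopifnot(sum(site_split) == n_total)
  truth <- if (model == "ordinal") {
    c(c(-1, 0, 1), rep(1, 4))
  } else {
    flatten_params(stacked_params(
      c(2, 3, 1), cbind(rep(0.5, 4), rep(2, 4), rep(1, 4))
    ))
  }
  structure(
    list(
      study = study, n_total = n_total, model = model,
      site_split = site_split, truth = truth,
      reps = as.integer(reps), seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# One replicate: generate, halve, deal to sites, fit, test, score.
run_one_rep <- function(design, rep_seed, g = 10L, hl_rule = "all") {
  model <- design$model
  n <- design$n_total
  data <- if (model == "ordinal") {
    gen_ordinal(n, seed = rep_seed)
  } else {
    gen_multinomial(n, seed = rep_seed)
  }
  n_fit <- sum(ceiling(design$site_split / 2))
  fit_sizes <- ceiling(design$site_split / 2)
  fit_pool <- grid_dataset(data$y[seq_len(n_fit)],
    data$X[seq_len(n_fit), , drop = FALSE],
    K = data$K
  )
  eval_idx <- (n_fit + 1L):n
  y_eval <- data$y[eval_idx]
  X_eval <- data$X[eval_idx, , drop = FALSE]
  sites <- split_dataset(fit_pool, fit_sizes)

  fit <- grid_newton(model, sites)
  if (!fit$converged) stop("replicate did not converge")
  out <- list(
    estimate = unname(fit$params),
    se_model = sqrt(diag(fit$vcov)),
    iterations = fit$iterations
  )
  if (model == "ordinal") {
    out$poa_pvalue <- score_test_po(fit, sites)$pvalue
    cum <- predict(fit, X_eval, type = "cumulative")
    hl <- ordinal_hl_battery(y_eval, cum, g = g, rule = hl_rule)
    out$hl_pass <- hl$pass
    out$hl_pvalues <- hl$pvalues
    out$auc <- auc_ordinal_mean(y_eval, cum)
  } else {
    probs <- predict(fit, X_eval, type = "class_probs")
    ehl <- hl_extended(y_eval, probs, g = g)
    out$hl_pass <- ehl$pvalue >= 0.05
    out$hl_pvalues <- ehl$pvalue
    out$auc <- auc_hand_till(y_eval, probs)
  }
  out
}

#' Run a full Monte-Carlo study
#'
#' For each replicate: generate the pooled stream, halve it into fitting and
#' evaluation parts, deal the fitting half to sites, grid-fit the model,
#' run the proportional-odds score test (ordinal studies), the per-collapse
#' Hosmer-Lemeshow battery (ordinal) or the extended HL test (multinomial)
#' and the matching AUC on the pooled evaluation half. Replicates that fail
#' to converge are counted and excluded from the summaries.
#'
#' @param design A [study_design()].
#' @param g Hosmer-Lemeshow group count (default 10).
#' @param hl_rule Overall verdict rule for the ordinal HL battery
#'   (`"all"` or `"any"`; see [ordinal_hl_battery()]).
#' @param progress Print a dot every 100 replicates.
#' @return A list of class `study_summary`: `estimates` (reps x p matrix),
#'   `bias`, `se` (empirical SD across replicates), `se_model_mean` (mean of
#'   model-based standard errors), `truth`, `poa_rate`, `hl_rate`,
#'   `poa_and_hl_rate`, `auc` (per-replicate values), `n_failed`, `design`.
#' @export
run_study <- function(design, g = 10L, hl_rule = "all", progress = FALSE) {
  stopifnot(inherits(design, "study_design"))
  reps <- design$reps
  p <- length(design$truth)
  est <- matrix(NA_real_, reps, p)
  sem <- matrix(NA_real_, reps, p)
  poa <- rep(NA_real_, reps)
  hlp <- rep(NA, reps)
  auc <- rep(NA_real_, reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      run_one_rep(design, design$seed + r, g = g, hl_rule = hl_rule),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    est[r, ] <- res$estimate
    sem[r, ] <- res$se_model
    if (design$model == "ordinal") poa[r] <- res$poa_pvalue
    hlp[r] <- res$hl_pass
    auc[r] <- res$auc
    if (progress && r %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  ok <- !is.na(est[, 1L])
  nm <- if (design$model == "ordinal") {
    param_names("ordinal", 4L, 4L)
  } else {
    param_names("multinomial", 4L, 4L)
  }
  colnames(est) <- colnames(sem) <- nm
  bias <- colMeans(est[ok, , drop = FALSE]) - design$truth
  se <- apply(est[ok, , drop = FALSE], 2L, stats::sd)
  poa_rate <- if (design$model == "ordinal") mean(poa[ok] >= 0.05) else NA_real_
  hl_rate <- mean(hlp[ok])
  both <- if (design$model == "ordinal") {
    mean(poa[ok] >= 0.05 & hlp[ok])
  } else {
    NA_real_
  }
  structure(
    list(
      estimates = est[ok, , drop = FALSE], bias = bias, se = se,
      se_model_mean = colMeans(sem[ok, , drop = FALSE]),
      truth = stats::setNames(design$truth, nm),
      poa_rate = poa_rate, hl_rate = hl_rate, poa_and_hl_rate = both,
      poa_pvalues = if (design$model == "ordinal") poa[ok] else NULL,
      auc = auc[ok], n_failed = failed, design = design
    ),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Study %d (%s, n = %d, split %s, %d reps, %d failed)\n",
    d$study, d$model, d$n_total,
    paste(d$site_split, collapse = "/"), d$reps, x$n_failed
  ))
  tab <- data.frame(
    true = x$truth, bias = signif(x$bias, 3), se = signif(x$se, 3)
  )
  print(tab)
  if (!is.na(x$poa_rate)) {
    cat(sprintf(
      "POA pass rate %.3f | HL pass rate %.3f | both %.3f\n",
      x$poa_rate, x$hl_rate, x$poa_and_hl_rate
    ))
  } else {
    cat(sprintf("EHL pass rate %.3f\n", x$hl_rate))
  }
  cat(sprintf("mean AUC %.3f\n", mean(x$auc)))
  invisible(x)
}
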