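# The grid (federated) fitting protocol. Each round, every site evaluates its
# local log-likelihood, gradient and Hessian at the current parameter vector
# (site_summary); the coordinator sums them (aggregate_summaries) and takes a
# Newton step. Because all three likelihoods decompose over observations, the
# aggregated derivatives equal the pooled-data derivatives exactly, so the
# grid fit is identical to the centralized fit.

#' Newton iteration settings
#'
#' @param tol Convergence tolerance on the maximum absolute parameter change
#'   per accepted step (default `1e-6`).
#' @param max_iter Maximum number of Newton rounds (default 25; well-behaved
#'   problems converge in under 15).
#' @param step_halving_max Maximum number of times a rejected step is halved
#'   before the iteration gives up (default 10).
#' @return A list of class `newton_config`.
#' @export
newton_config <- function(tol = 1e-6, max_iter = 25L, step_halving_max = 10L) {
  stopifnot(tol > 0, max_iter >= 1L, step_halving_max >= 0L)
  structure(
    list(
      tol = tol, max_iter = as.integer(max_iter),
      step_halving_max = as.integer(step_halving_max)
    ),
    class = "newton_config"
  )
}

# Decimal fingerprint of a parameter vector: 17 significant digits uniquely
# identify a double, so two vectors hash equal iff they are bit-identical.
param_hash <- function(params) {
  paste(formatC(as.numeric(params), digits = 17, format = "g"),
    collapse = ","
  )
}

#' Evaluate one site's summary at a parameter vector
#'
#' This is the only quantity a site ever transmits: its local log-likelihood,
#' gradient, Hessian and observation count at the coordinator's current
#' parameter value. No observation-level data leave the site.
#'
#' @param model One of `"ordinal"`, `"gol"`, `"multinomial"`.
#' @param params Flattened parameter vector (or a parameter object).
#' @param data The site's [grid_dataset()].
#' @param site_id Optional site label carried in error messages and the JSON
#'   message format.
#' @return A list of class `site_summary` with elements `loglik`, `gradient`,
#'   `hessian`, `n_site`, `param_hash` and `site_id`.
#' @export
site_summary <- function(model, params, data, site_id = NA) {
  stopifnot(inherits(data, "grid_dataset"))
  theta <- flatten_params(params)
  d <- withCallingHandlers(
    model_eval(model, theta, data),
    gridlogit_nonfinite = function(e) {
      if (!is.na(site_id)) {
        e$message <- paste0(e$message, " (site ", site_id, ")")
      }
      stop(e)
    }
  )
  structure(
    list(
      loglik = d$loglik, gradient = d$gradient, hessian = d$hessian,
      n_site = data$n, param_hash = param_hash(theta), site_id = site_id
    ),
    class = "site_summary"
  )
}

#' Aggregate site summaries into the pooled summary
#'
#' Element-wise sums of log-likelihood, gradient and Hessian over sites. All
#' summaries must have been evaluated at the same parameter vector; a hash
#' mismatch signals a stale summary from an out-of-sync round.
#'
#' @param summaries A list of [site_summary()] objects.
#' @return A single `site_summary` with `n_site` the total observation count.
#' @export
aggregate_summaries <- function(summaries) {
  if (!length(summaries)) stop("aggregate_summaries: no summaries supplied")
  stopifnot(all(vapply(summaries, inherits, TRUE, "site_summary")))
  hashes <- vapply(summaries, `[[`, "", "param_hash")
  if (length(unique(hashes)) != 1L) {
    stop("aggregate_summaries: stale summary - parameter hashes differ across sites")
  }
  dims <- vapply(summaries, function(s) length(s$gradient), 1L)
  if (length(unique(dims)) != 1L) {
    stop("aggregate_summaries: protocol error - gradient dimensions differ")
  }
  out <- summaries[[1L]]
  for (s in summaries[-1L]) {
    out$loglik <- out$loglik + s$loglik
    out$gradient <- out$gradient + s$gradient
    out$hessian <- out$hessian + s$hessian
    out$n_site <- out$n_site + s$n_site
  }
  out$site_id <- NA
  out
}

# Feasible starting values computed from pooled per-site category counts
# (the one preliminary exchange before derivative rounds): ordinal starts at
# the empirical cumulative logits with zero slopes; the stacked models start
# at the empirical baseline-category log odds with zero slopes.
default_init <- function(model, sites) {
  K <- sites[[1L]]$K
  m <- sites[[1L]]$m
  counts <- Reduce(`+`, lapply(sites, function(d) tabulate(d$y, nbins = K)))
  if (any(counts == 0L)) {
    stop(
      "default_init: pooled data have no observations in category ",
      which(counts == 0L)[1L]
    )
  }
  n <- sum(counts)
  if (model == "ordinal") {
    cum <- cumsum(counts)[seq_len(K - 1L)] / n
    c(stats::qlogis(cum), rep(0, m))
  } else {
    alpha0 <- log(counts[seq_len(K - 1L)] / counts[K])
    as.numeric(rbind(alpha0, matrix(0, m, K - 1L)))
  }
}

#' Grid Newton fit of an ordinal or multinomial model across sites
#'
#' Iterates the two-step protocol - sites evaluate local derivatives, the
#' coordinator aggregates and updates - until the maximum absolute parameter
#' change drops below `config$tol`. A proposed step that yields a non-finite
#' likelihood or lowers the aggregated log-likelihood is halved up to
#' `config$step_halving_max` times (pure Newton never needs this at
#' reasonable sample sizes; it guards small or degenerate sites). The
#' variance-covariance matrix is the negative inverse of the aggregated
#' Hessian at the optimum.
#'
#' @param model One of `"ordinal"`, `"multinomial"`, `"gol"`.
#' @param sites A list of [grid_dataset()] objects (a single dataset is
#'   treated as one site, i.e. the centralized fit).
#' @param init Optional starting parameter vector or parameter object. The
#'   default starts from pooled empirical category frequencies with zero
#'   slopes.
#' @param config A [newton_config()].
#' @param verbose Print one coordinator log line per round.
#' @return An object of class `grid_fit`: a list with `params` (named
#'   estimate vector), `vcov`, `loglik`, `n_total`, `iterations`,
#'   `converged`, `trace` (per-round max-abs update), `model`, `K`, `m`.
#' @examples
#' sites <- split_dataset(gen_ordinal(300, seed = 1), c(100, 100, 100))
#' fit <- grid_newton("ordinal", sites)
#' coef(fit)
#' @export
grid_newton <- function(model, sites, init = NULL,
                        config = newton_config(), verbose = FALSE) {
  if (inherits(sites, "grid_dataset")) sites <- list(sites)
  stopifnot(length(sites) >= 1L, all(vapply(sites, inherits, TRUE, "grid_dataset")))
  K <- sites[[1L]]$K
  m <- sites[[1L]]$m
  if (!all(vapply(sites, function(d) d$K == K && d$m == m, TRUE))) {
    stop("grid_newton: all sites must share the same K and m")
  }
  theta <- if (is.null(init)) default_init(model, sites) else flatten_params(init)
  if (length(theta) != n_params(model, K, m)) {
    stop("grid_newton: init has wrong length for this model")
  }

  eval_round <- function(th) {
    aggregate_summaries(lapply(seq_along(sites), function(u) {
      site_summary(model, th, sites[[u]], site_id = u)
    }))
  }

  agg <- eval_round(theta) # init must be feasible; error here is fatal
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(
      solve(agg$hessian, agg$gradient),
      error = function(e) {
        stop(
          "grid_newton: aggregated Hessian is singular ",
          "(separation or unidentifiable model): ", conditionMessage(e)
        )
      }
    )
    step <- 1
    accepted <- FALSE
    for (half in 0:config$step_halving_max) {
      theta_try <- theta - step * delta
      agg_try <- tryCatch(eval_round(theta_try),
        gridlogit_nonfinite = function(e) NULL
      )
      # tiny slack keeps rounding noise at convergence from forcing halvings
      if (!is.null(agg_try) &&
        agg_try$loglik >= agg$loglik - 1e-10 * (1 + abs(agg$loglik))) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      warning("grid_newton: step-halving exhausted at iteration ", iter)
      break
    }
    change <- max(abs(theta_try - theta))
    trace <- c(trace, change)
    theta <- theta_try
    agg <- agg_try
    if (verbose) {
      message(sprintf(
        "round %2d  loglik %14.6f  max|update| %.3e", iter, agg$loglik, change
      ))
    }
    if (change < config$tol) {
      converged <- TRUE
      break
    }
  }

  vcov <- -solve(agg$hessian)
  nm <- param_names(model, K, m, colnames(sites[[1L]]$X))
  names(theta) <- nm
  dimnames(vcov) <- list(nm, nm)
  structure(
    list(
      params = theta, vcov = vcov, loglik = agg$loglik,
      n_total = agg$n_site, iterations = iter, converged = converged,
      trace = trace, model = model, K = K, m = m
    ),
    class = "grid_fit"
  )
}

param_names <- function(model, K, m, xnames = NULL) {
  if (is.null(xnames)) xnames <- paste0("x", seq_len(m))
  if (model == "ordinal") {
    c(paste0("alpha", seq_len(K - 1L)), xnames)
  } else {
    as.vector(vapply(
      seq_len(K - 1L),
      function(w) c(paste0("alpha", w), paste0(xnames, ".", w)),
      character(m + 1L)
    ))
  }
}

#' Wald coefficient table for a grid fit
#'
#' @param fit A converged [grid_newton()] fit.
#' @return A data frame with one row per coefficient: `term`, `estimate`,
#'   `se` (square root of the variance-covariance diagonal), `z`
#'   (`estimate/se`) and `p` (two-sided standard-normal tail probability).
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "grid_fit"))
  if (!fit$converged) stop("wald_table: fit did not converge")
  v <- diag(fit$vcov)
  if (any(v <= 0)) {
    stop("wald_table: nonpositive variance for term ", names(v)[v <= 0][1L])
  }
  se <- sqrt(v)
  z <- fit$params / se
  data.frame(
    term = names(fit$params), estimate = unname(fit$params),
    se = unname(se), z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
}

#' @export
coef.grid_fit <- function(object, ...) object$params

#' @export
vcov.grid_fit <- function(object, ...) object$vcov

#' @export
logLik.grid_fit <- function(object, ...) {
  structure(object$loglik,
    df = length(object$params), nobs = object$n_total,
    class = "logLik"
  )
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf(
    "<grid_fit> %s model, K = %d, n = %d, loglik = %.4f (%d rounds%s)\n",
    x$model, x$K, x$n_total, x$loglik, x$iterations,
    if (x$converged) "" else ", NOT converged"
  ))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
summary.grid_fit <- function(object, ...) {
  tab <- wald_table(object)
  cat(sprintf(
    "%s model fit across sites: n = %d, loglik = %.4f, %d Newton rounds\n\n",
    object$model, object$n_total, object$loglik, object$iterations
  ))
  printed <- tab
  printed$estimate <- sprintf("%.3f", printed$estimate)
  printed$se <- sprintf("%.3f", printed$se)
  printed$z <- sprintf("%.3f", printed$z)
  printed$p <- sprintf("%.3f", printed$p)
  print(printed, row.names = FALSE)
  invisible(tab)
}

#' Serialize a site summary to the wire format
#'
#' One JSON object per site per round: model identifier, parameter hash,
#' local log-likelihood, gradient, row-major Hessian, observation count,
#' site id and round index. Numbers are written with 17 significant digits,
#' so deserialization is bit-exact.
#'
#' @param s A [site_summary()].
#' @param model Model identifier carried in the message.
#' @param round Round index.
#' @return A JSON string.
#' @export
site_summary_to_json <- function(s, model = NA, round = NA) {
  stopifnot(inherits(s, "site_summary"))
  jsonlite::toJSON(
    list(
      model = model, loglik = s$loglik, gradient = s$gradient,
      hessian = as.numeric(t(s$hessian)), dim = nrow(s$hessian),
      n_site = s$n_site, param_hash = s$param_hash,
      site_id = s$site_id, round = round
    ),
    auto_unbox = TRUE, digits = I(17), na = "null"
  )
}

#' Deserialize a site summary from the wire format
#'
#' @param json A JSON string produced by [site_summary_to_json()].
#' @return A [site_summary()] object.
#' @export
site_summary_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  d <- x$dim
  structure(
    list(
      loglik = x$loglik, gradient = as.numeric(x$gradient),
      hessian = matrix(as.numeric(x$hessian), d, d, byrow = TRUE),
      n_site = as.integer(x$n_site), param_hash = x$param_hash,
      site_id = if (is.null(x$site_id)) NA else x$site_id
    ),
    class = "site_summary"
  )
}
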