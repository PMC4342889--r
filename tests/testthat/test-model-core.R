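test_that("cumulative probabilities follow the logistic closed form", {
  p <- ordinal_cumulative_probs(ordinal_params(c(-1, 1), 0), matrix(2.5))
  expect_equal(drop(p), c(plogis(-1), plogis(1)), tolerance = 1e-12)
  expect_equal(unname(p[1, ]), c(0.26894, 0.73106), tolerance = 1e-4)

  # zero linear predictor gives 1/2 regardless of x
  p0 <- ordinal_cumulative_probs(
    ordinal_params(c(0, 0), c(0, 0, 0)), matrix(rnorm(9), 3)
  )
  expect_true(all(p0 == 0.5))

  # the ordinal study DGP at the origin
  p1 <- ordinal_cumulative_probs(
    ordinal_params(c(-1, 0, 1), rep(1, 4)), matrix(0, 1, 4)
  )
  expect_equal(drop(p1), plogis(c(-1, 0, 1)), tolerance = 1e-12)

  expect_error(
    ordinal_cumulative_probs(ordinal_params(c(-1, 1), c(1, 1)), matrix(0, 1, 3)),
    "ncol"
  )
})

test_that("cumulative probabilities are stable at extreme linear predictors", {
  p <- ordinal_cumulative_probs(
    ordinal_params(c(-650, 650), 1), matrix(c(-50, 0, 50))
  )
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("ordinal log-likelihood matches the closed form on one observation", {
  d <- grid_dataset(2L, matrix(0, 1, 1), K = 3L)
  dv <- ordinal_derivatives(ordinal_params(c(-1, 1), 0), d)
  expect_equal(dv$loglik, log(plogis(1) - plogis(-1)), tolerance = 1e-12)
  expect_equal(dv$loglik, -0.77199, tolerance = 1e-4)
})

test_that("analytic ordinal derivatives match finite differences", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_ordinal_instance()
    th <- flatten_params(inst$params)
    K <- inst$data$K
    m <- inst$data$m
    f <- function(t) ordinal_derivatives(unflatten_ordinal(t, K, m), inst$data)$loglik
    gf <- function(t) ordinal_derivatives(unflatten_ordinal(t, K, m), inst$data)$gradient
    dv <- ordinal_derivatives(inst$params, inst$data)
    expect_lt(max(abs(dv$gradient - fd_gradient(f, th))), 1e-6)
    expect_lt(max(abs(dv$hessian - fd_jacobian(gf, th))), 1e-4)
    expect_lt(max(abs(dv$hessian - t(dv$hessian))), 1e-10)
    expect_lte(dv$loglik, 0) # sum of log category probabilities
  }
})

test_that("generalized ordered logit restricted to shared slopes equals the ordinal model", {
  set.seed(202)
  inst <- random_ordinal_instance(n = 60)
  psi <- embed_ordinal_in_gol(inst$params)
  do <- ordinal_derivatives(inst$params, inst$data)
  dg <- gol_derivatives(psi, inst$data)
  expect_identical(dg$loglik, do$loglik)
})

test_that("analytic gol derivatives match finite differences on monotone configurations", {
  set.seed(303)
  for (i in 1:20) {
    inst <- random_ordinal_instance()
    K <- inst$data$K
    m <- inst$data$m
    # perturb the embedded point slightly; small jitter keeps cumulative
    # probabilities monotone on the sampled covariates
    psi <- flatten_params(embed_ordinal_in_gol(inst$params)) +
      rnorm((K - 1) * (m + 1), 0, 0.02)
    f <- function(t) gol_derivatives(unflatten_stacked(t, K, m), inst$data)$loglik
    gf <- function(t) gol_derivatives(unflatten_stacked(t, K, m), inst$data)$gradient
    dv <- gol_derivatives(unflatten_stacked(psi, K, m), inst$data)
    expect_lt(max(abs(dv$gradient - fd_gradient(f, psi))), 1e-6)
    expect_lt(max(abs(dv$hessian - fd_jacobian(gf, psi))), 1e-4)
  }
})

test_that("gol likelihood equals the direct category-probability product on a tiny case", {
  # K = 3, m = 1, n = 2: category probabilities assembled by hand from the
  # two split-specific logistic curves
  psi <- stacked_params(alpha = c(-0.5, 0.7), beta = matrix(c(0.8, 0.4), 1))
  d <- grid_dataset(c(2L, 3L), matrix(c(0.3, -1.2)), K = 3L)
  p_le1 <- plogis(-0.5 + 0.8 * c(0.3, -1.2))
  p_le2 <- plogis(0.7 + 0.4 * c(0.3, -1.2))
  expected <- log(p_le2[1] - p_le1[1]) + log(1 - p_le2[2])
  expect_equal(gol_derivatives(psi, d)$loglik, expected, tolerance = 1e-12)
})

test_that("gol rejects non-monotone cumulative probabilities with the offending row", {
  psi <- stacked_params(alpha = c(2, -2), beta = matrix(c(0, 0), 1))
  d <- grid_dataset(c(2L, 1L), matrix(c(0, 0)), K = 3L)
  err <- tryCatch(gol_derivatives(psi, d), condition = identity)
  expect_s3_class(err, "gridlogit_nonfinite")
  expect_equal(err$row, 1L)
})

test_that("multinomial probabilities are normalized and stabilized", {
  pars0 <- stacked_params(rep(0, 3), matrix(0, 4, 3))
  p0 <- multinomial_probs(pars0, matrix(rnorm(8), 2))
  expect_true(all(abs(p0 - 0.25) < 1e-14))

  # multinomial study DGP at the origin
  pars <- stacked_params(c(2, 3, 1), cbind(rep(.5, 4), rep(2, 4), rep(1, 4)))
  p <- multinomial_probs(pars, matrix(0, 1, 4))
  expect_equal(
    drop(p), exp(c(2, 3, 1, 0)) / sum(exp(c(2, 3, 1, 0))),
    tolerance = 1e-12
  )
  expect_equal(drop(p), c(0.23687, 0.64391, 0.08714, 0.03206), tolerance = 1e-4)

  set.seed(404)
  for (i in 1:100) {
    pr <- multinomial_probs(
      stacked_params(rnorm(3, 0, 3), matrix(rnorm(6, 0, 3), 2)),
      matrix(rnorm(10), 5)
    )
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)
    expect_true(all(pr > 0 & pr < 1))
  }

  # huge linear predictors must not overflow
  pbig <- multinomial_probs(
    stacked_params(c(800, -800, 0), matrix(0, 1, 3)), matrix(0, 1, 1)
  )
  expect_true(all(is.finite(pbig)))
})

test_that("analytic multinomial derivatives match finite differences", {
  set.seed(505)
  for (i in 1:20) {
    inst <- random_multinomial_instance()
    psi <- flatten_params(inst$params)
    K <- inst$data$K
    m <- inst$data$m
    f <- function(t) multinomial_derivatives(unflatten_stacked(t, K, m), inst$data)$loglik
    gf <- function(t) multinomial_derivatives(unflatten_stacked(t, K, m), inst$data)$gradient
    dv <- multinomial_derivatives(inst$params, inst$data)
    expect_lt(max(abs(dv$gradient - fd_gradient(f, psi))), 1e-6)
    expect_lt(max(abs(dv$hessian - fd_jacobian(gf, psi))), 1e-4)
    # negative semidefinite at any parameter value
    expect_lte(max(eigen(dv$hessian, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  }
})

test_that("multinomial log-likelihood closed forms and permutation invariance", {
  d1 <- grid_dataset(4L, matrix(0, 1, 2), K = 4L)
  dv <- multinomial_derivatives(stacked_params(rep(0, 3), matrix(0, 2, 3)), d1)
  expect_equal(dv$loglik, log(0.25), tolerance = 1e-12)

  set.seed(606)
  inst <- random_multinomial_instance(n = 30)
  perm <- sample(inst$data$n)
  dperm <- grid_dataset(inst$data$y[perm], inst$data$X[perm, ], K = inst$data$K)
  expect_equal(
    multinomial_derivatives(inst$params, dperm)$loglik,
    multinomial_derivatives(inst$params, inst$data)$loglik,
    tolerance = 1e-12
  )
})

test_that("ordinal category probabilities sum to one across categories", {
  set.seed(707)
  inst <- random_ordinal_instance(n = 25)
  P <- ordinal_cumulative_probs(inst$params, inst$data$X)
  cat_probs <- cbind(P, 1) - cbind(0, P)
  expect_lt(max(abs(rowSums(cat_probs) - 1)), 1e-12)
  expect_true(all(cat_probs > 0))
})

test_that("embedding the ordinal fit in the stacked space is definitional", {
  th <- ordinal_params(c(-0.3, 0.9), c(1.5, -2.5))
  psi <- embed_ordinal_in_gol(th)
  expect_equal(
    flatten_params(psi),
    c(-0.3, 1.5, -2.5, 0.9, 1.5, -2.5)
  )

  truth <- ordinal_params(c(-1, 0, 1), rep(1, 4))
  flat <- flatten_params(embed_ordinal_in_gol(truth))
  expect_length(flat, 15)
  expect_equal(matrix(flat, 5)[-1, ], matrix(1, 4, 3))

  set.seed(808)
  inst <- random_ordinal_instance()
  expect_identical(
    gol_derivatives(embed_ordinal_in_gol(inst$params), inst$data)$loglik,
    ordinal_derivatives(inst$params, inst$data)$loglik
  )
})

test_that("invalid category probabilities raise the non-finite likelihood error", {
  # y = 3 but Pr(Y <= 2) == Pr(Y <= 1): middle category has probability 0
  d <- grid_dataset(c(1L, 2L, 2L), matrix(0, 3, 1), K = 3L)
  err <- tryCatch(
    ordinal_derivatives(ordinal_params(c(0, 0), 1), d),
    condition = identity
  )
  expect_s3_class(err, "gridlogit_nonfinite")
  expect_equal(err$row, 2L)
})
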