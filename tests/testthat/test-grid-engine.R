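test_that("a single-observation site summary equals the model derivatives on that row", {
  set.seed(11)
  inst <- random_ordinal_instance(n = 20)
  d1 <- grid_dataset(inst$data$y[1], inst$data$X[1, , drop = FALSE], K = inst$data$K)
  th <- flatten_params(inst$params)
  s <- site_summary("ordinal", th, d1)
  dv <- ordinal_derivatives(inst$params, d1)
  expect_identical(s$loglik, dv$loglik)
  expect_identical(s$gradient, dv$gradient)
  expect_identical(s$hessian, dv$hessian)
  expect_equal(s$n_site, 1L)
})

test_that("site summaries are additive over arbitrary partitions", {
  set.seed(22)
  for (model in c("ordinal", "multinomial")) {
    inst <- if (model == "ordinal") {
      random_ordinal_instance(n = 60)
    } else {
      random_multinomial_instance(n = 60)
    }
    th <- flatten_params(inst$params)
    whole <- site_summary(model, th, inst$data)
    cuts <- sort(sample(10:50, 2))
    sizes <- diff(c(0, cuts, 60))
    parts <- split_dataset(inst$data, sizes)
    agg <- aggregate_summaries(
      lapply(parts, function(p) site_summary(model, th, p))
    )
    expect_equal(agg$loglik, whole$loglik, tolerance = 1e-10)
    expect_equal(agg$gradient, whole$gradient, tolerance = 1e-10)
    expect_equal(agg$hessian, whole$hessian, tolerance = 1e-10)
    expect_equal(agg$n_site, whole$n_site)
  }
})

test_that("aggregation is an identity for one site and permutation-invariant", {
  set.seed(33)
  inst <- random_ordinal_instance(n = 30)
  th <- flatten_params(inst$params)
  s <- site_summary("ordinal", th, inst$data)
  expect_identical(aggregate_summaries(list(s))$loglik, s$loglik)

  parts <- split_dataset(inst$data, c(10, 8, 12))
  sums <- lapply(parts, function(p) site_summary("ordinal", th, p))
  a123 <- aggregate_summaries(sums)
  a321 <- aggregate_summaries(rev(sums))
  expect_equal(a123$gradient, a321$gradient, tolerance = 1e-10)
  expect_equal(a123$hessian, a321$hessian, tolerance = 1e-10)
})

test_that("stale or mismatched summaries are rejected", {
  set.seed(44)
  inst <- random_ordinal_instance(n = 20)
  th <- flatten_params(inst$params)
  parts <- split_dataset(inst$data, c(10, 10))
  s1 <- site_summary("ordinal", th, parts[[1]])
  s2 <- site_summary("ordinal", th + 1e-9, parts[[2]])
  expect_error(aggregate_summaries(list(s1, s2)), "stale")
  expect_false(s1$param_hash == s2$param_hash)
  expect_identical(
    s1$param_hash,
    site_summary("ordinal", th, parts[[2]])$param_hash
  )
})

test_that("grid fit equals the centralized fit round-for-round", {
  d <- gen_ordinal(400, seed = 55)
  sites <- split_dataset(d, c(50, 150, 200))
  fg <- grid_newton("ordinal", sites)
  fc <- grid_newton("ordinal", d)
  expect_identical(fg$iterations, fc$iterations)
  expect_lt(max(abs(fg$params - fc$params)), 1e-8)
  expect_lt(max(abs(fg$trace - fc$trace)), 1e-8)
  expect_equal(fg$loglik, fc$loglik, tolerance = 1e-10)
})

test_that("the estimate is invariant to how the data are partitioned", {
  for (model in c("ordinal", "multinomial")) {
    d <- if (model == "ordinal") {
      gen_ordinal(600, seed = 66)
    } else {
      gen_multinomial(600, seed = 66)
    }
    f1 <- grid_newton(model, split_dataset(d, c(200, 200, 200)))
    f2 <- grid_newton(model, split_dataset(d, c(20, 30, 550)))
    expect_lt(max(abs(f1$params - f2$params)), 1e-8)
    expect_lt(max(abs(f1$vcov - f2$vcov)), 1e-8)
  }
})

test_that("grid MLEs agree with independent reference fits", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nnet")
  d <- gen_ordinal(800, seed = 77)
  fit <- grid_newton("ordinal", split_dataset(d, c(300, 500)))
  df <- data.frame(y = factor(d$y), d$X)
  ref <- MASS::polr(y ~ x1 + x2 + x3 + x4, data = df, Hess = TRUE)
  # polr models zeta_w - beta' x, so its slopes are the negation of ours
  expect_equal(unname(coef(fit)[4:7]), unname(-coef(ref)), tolerance = 1e-4)
  expect_equal(unname(coef(fit)[1:3]), unname(ref$zeta), tolerance = 1e-4)

  dm <- gen_multinomial(800, seed = 78)
  fm <- grid_newton("multinomial", split_dataset(dm, c(400, 400)))
  dfm <- data.frame(y = relevel(factor(dm$y), ref = "4"), dm$X)
  refm <- nnet::multinom(y ~ x1 + x2 + x3 + x4,
    data = dfm, trace = FALSE, maxit = 500, reltol = 1e-14
  )
  expect_equal(
    matrix(unname(coef(fm)), 5, 3), unname(t(coef(refm))),
    tolerance = 1e-5
  )
})

test_that("accepted Newton rounds never decrease the aggregated log-likelihood", {
  d <- gen_ordinal(300, seed = 88)
  sites <- split_dataset(d, c(100, 200))
  fit <- grid_newton("ordinal", sites)
  init <- gridlogit:::default_init("ordinal", sites)
  ll0 <- aggregate_summaries(
    lapply(sites, function(s) site_summary("ordinal", init, s))
  )$loglik
  expect_gte(fit$loglik, ll0)
  expect_true(fit$converged)
  expect_lt(utils::tail(fit$trace, 1), 1e-6)
})

test_that("the fitted variance-covariance matrix matches a finite-difference information", {
  set.seed(99)
  inst <- random_ordinal_instance(n = 120)
  fit <- grid_newton("ordinal", inst$data)
  th <- unname(fit$params)
  K <- inst$data$K
  m <- inst$data$m
  gf <- function(t) ordinal_derivatives(unflatten_ordinal(t, K, m), inst$data)$gradient
  H_fd <- fd_jacobian(gf, th)
  V_fd <- solve(-(H_fd + t(H_fd)) / 2)
  expect_lt(max(abs(fit$vcov - V_fd)) / max(abs(V_fd)), 1e-4)
  expect_true(all(diag(fit$vcov) > 0))
})

test_that("wald_table reproduces the published z-value arithmetic", {
  d <- gen_ordinal(500, seed = 111)
  fit <- grid_newton("ordinal", d)
  tab <- wald_table(fit)
  expect_equal(tab$z, tab$estimate / tab$se, tolerance = 1e-12)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)), tolerance = 1e-12)
  # spot checks at the printed precision of the worked examples
  expect_equal(round(-1.028 / 0.318, 3), -3.233)
  expect_equal(round(2 * pnorm(-abs(-1.028 / 0.318)), 3), 0.001)
  expect_equal(round(2.456 / 0.775, 3), 3.169) # printed 3.168: rounded inputs
  # a zero estimate gives z = 0 and p = 1 by construction
  expect_equal(2 * pnorm(-abs(0 / 1.5)), 1)
})

test_that("site summaries survive the JSON wire format bit-exactly", {
  set.seed(123)
  inst <- random_multinomial_instance(n = 25)
  th <- flatten_params(inst$params)
  s <- site_summary("multinomial", th, inst$data, site_id = 2)
  back <- site_summary_from_json(site_summary_to_json(s, model = "multinomial", round = 3))
  expect_identical(back$loglik, s$loglik)
  expect_identical(back$gradient, s$gradient)
  expect_identical(back$hessian, s$hessian)
  expect_identical(back$param_hash, s$param_hash)
  expect_identical(back$n_site, s$n_site)
})

test_that("an unconverged fit is flagged and refuses a Wald table", {
  set.seed(321)
  y <- rep(1:4, each = 15)
  d <- grid_dataset(y, matrix(rnorm(60), 60, 1), K = 4L)
  f <- grid_newton("ordinal", d, config = newton_config(tol = 1e-14, max_iter = 1))
  expect_false(f$converged)
  expect_error(wald_table(f), "converge")
})
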