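test_that("Poisson log-likelihood matches closed forms", {
  panel <- cellwise_panel(Y = 0L, E = 1)
  expect_equal(log_likelihood(panel, list(alpha = 0)), -1.0)

  panel2 <- cellwise_panel(Y = 2L, E = 1)
  expect_equal(log_likelihood(panel2, list(alpha = 0)),
               2 * 0 - 1 - log(2))
  # cross-check against dpois
  expect_equal(log_likelihood(panel2, list(alpha = 0.3)),
               dpois(2, exp(0.3), log = TRUE))
})

test_that("likelihood is invariant under the alpha/u translation symmetry", {
  panel <- cellwise_panel(Y = c(3L, 1L, 4L), E = c(1, 2, 1.5))
  base <- list(alpha = 0.2, u = c(0.1, -0.3, 0.2))
  shifted <- list(alpha = 0.2 + 0.7, u = base$u - 0.7)
  expect_equal(log_likelihood(panel, base),
               log_likelihood(panel, shifted))
})

test_that("non-finite linear predictors are reported with their cell", {
  panel <- cellwise_panel(Y = c(1L, 1L), E = c(1, 1))
  expect_error(log_likelihood(panel, list(alpha = 0, u = c(Inf, 0))),
               "tract T1")
})

test_that("ICAR log density matches its quadratic form", {
  # constant field: zero quadratic form
  ld <- icar_logdensity(c(2, 2, 2), cbind(c(1, 2), c(2, 3)),
                        precision = 1)
  expect_equal(attr(ld, "quad"), 0)

  # two nodes, one edge, values (1, -1), tau = 1:
  # (n - c)/2 log tau = 0, quadratic part -(1/2) * (2)^2 = -2
  ld2 <- icar_logdensity(c(1, -1), cbind(1, 2), precision = 1)
  expect_equal(as.numeric(ld2), -2.0)

  # 4-cycle: match the dense precision-matrix form -(1/2) u' Q u
  edges <- cbind(1:4, c(2, 3, 4, 1))
  u <- c(0.5, -0.2, 0.4, -0.7)
  u <- u - mean(u)
  tau <- 1.7
  A <- matrix(0, 4, 4); A[edges] <- 1; A[edges[, c(2, 1)]] <- 1
  Q <- tau * (diag(rowSums(A)) - A)
  expected <- (4 - 1) / 2 * log(tau) - 0.5 * t(u) %*% Q %*% u
  expect_equal(as.numeric(icar_logdensity(u, edges, tau)),
               as.numeric(expected))
})

test_that("precision full conditionals match the symbolic closed form", {
  # 3-node path graph: rank n - c = 2
  edges <- cbind(c(1, 2), c(2, 3))
  vals <- c(0.4, -0.1, -0.3)
  fc <- precision_fullcond(vals, edges, prior_shape = 2, prior_scale = 1)
  q <- (0.4 - (-0.1))^2 + ((-0.1) - (-0.3))^2
  expect_equal(fc$shape, 2 + 2 / 2)
  expect_equal(fc$rate, 1 + q / 2)

  # disconnected 3-node graph (one edge): rank 1
  fc2 <- precision_fullcond(vals, cbind(1, 2))
  expect_equal(fc2$shape, 2 + 1 / 2)

  # exchangeable effect: rank n, sum of squares
  fc3 <- precision_fullcond(vals, NULL)
  expect_equal(fc3$shape, 2 + 3 / 2)
  expect_equal(fc3$rate, 1 + sum(vals^2) / 2)

  # no data: the full conditional is the Gamma(2, scale 1) prior (mean 2)
  fc0 <- precision_fullcond(numeric(0), NULL)
  expect_equal(fc0$shape, 2)
  expect_equal(fc0$rate, 1)
})

test_that("identical seed, spec and panel reproduce the chain exactly", {
  sim <- simulate_study(small_config(seed = 21))
  panel <- build_panel(sim$records_complete, sim)
  spec <- model_spec(effects = c("u", "v"),
                     tract_covariates = c("cov01", "cov02"),
                     mcmc = mcmc_settings(n_iter = 300, n_burnin = 100,
                                          thin = 1, seed = 5))
  f1 <- suppressWarnings(sample_posterior(panel, spec))
  f2 <- suppressWarnings(sample_posterior(panel, spec))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$tau, f2$tau)
  # a different seed moves the chain
  spec3 <- spec; spec3$mcmc$seed <- 6L
  f3 <- suppressWarnings(sample_posterior(panel, spec3))
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("stored random effects satisfy their constraints at every draw", {
  sim <- simulate_study(small_config(seed = 22))
  panel <- build_panel(sim$records_complete, sim)
  spec <- model_spec(effects = c("u", "v", "w", "g"),
                     mcmc = mcmc_settings(n_iter = 250, n_burnin = 50,
                                          thin = 1, seed = 7))
  fit <- suppressWarnings(sample_posterior(panel, spec))
  expect_lt(max(abs(rowMeans(fit$u))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$w))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$g))), 1e-8)
  expect_true(all(fit$tau > 0))
})

test_that("a point-mass posterior makes CPO the exact likelihood", {
  Y <- c(2L, 0L, 5L, 1L, 3L, 2L)
  E <- rep(2, 6)
  panel <- cellwise_panel(Y, E)
  alpha <- 0.1
  ll <- dpois(Y, E * exp(alpha), log = TRUE)
  fake <- structure(list(
    cell_loglik = matrix(rep(ll, each = 120), nrow = 120),
    cells = list(n_i = 6, n_k = 1, n_j = 1, tract_of = 1:6,
                 year_of = rep(1L, 6))
  ), class = "bhm_samples")
  fs <- compute_cpo_lpml(panel, fake)
  expect_equal(as.vector(fs$cpo), exp(ll), tolerance = 1e-12)
  # single year: tract-averaged CPO equals the cellwise value
  expect_equal(fs$lpml, sum(ll), tolerance = 1e-12)
  expect_true(all(fs$cpo > 0 & fs$cpo <= 1))
})

test_that("LPML aggregation rules differ only in how cells are pooled", {
  withr::local_seed(81)
  Y <- matrix(c(2L, 3L, 1L, 0L, 4L, 2L), 3, 2)
  S <- 150
  ll <- matrix(rnorm(S * 6, -2, 0.1), S, 6)
  fake <- structure(list(
    cell_loglik = ll,
    cells = list(n_i = 3, n_k = 2, n_j = 1,
                 tract_of = rep(1:3, 2), year_of = rep(1:2, each = 3))
  ), class = "bhm_samples")
  panel <- list(Y = Y)
  f1 <- compute_cpo_lpml(panel, fake, method = "tract_annual")
  f2 <- compute_cpo_lpml(panel, fake, method = "cellwise")
  f3 <- compute_cpo_lpml(panel, fake, method = "annual_sum")
  logcpo <- log(f1$cpo)
  expect_equal(f2$lpml, sum(logcpo))
  expect_equal(f3$lpml, mean(colSums(logcpo)))
  expect_equal(f1$lpml, sum(log(rowMeans(f1$cpo))))
})

test_that("compare_models ranks within a dataset and records failures", {
  sim <- simulate_study(small_config(seed = 23))
  panel <- build_panel(sim$records_complete, sim)
  mc <- mcmc_settings(n_iter = 400, n_burnin = 200, thin = 1, seed = 9)
  specs <- list(
    good = model_spec(effects = "v", tract_covariates = c("cov01", "cov02"),
                      mcmc = mc),
    bad = model_spec(effects = "v", tract_covariates = "nope", mcmc = mc)
  )
  w <- testthat::capture_warnings(tab <- compare_models(panel, specs))
  expect_true(any(grepl("failed", w)))
  expect_true(tab$failed[tab$model == "bad"])
  expect_false(tab$failed[tab$model == "good"])
  expect_true(is.finite(tab$lpml[tab$model == "good"]))

  # identical specs tie within Monte-Carlo noise (same seed: exactly)
  specs2 <- list(a = specs$good, b = specs$good)
  tab2 <- suppressWarnings(compare_models(panel, specs2))
  expect_equal(tab2$lpml[1], tab2$lpml[2])
})

test_that("zero-variance forced covariates are rejected before sampling", {
  sim <- simulate_study(small_config(seed = 24))
  panel <- build_panel(sim$records_complete, sim)
  panel$X1 <- cbind(panel$X1, flat = 0)
  panel$x1_names <- colnames(panel$X1)
  spec <- model_spec(effects = character(), tract_covariates = "flat",
                     mcmc = mcmc_settings(n_iter = 200, n_burnin = 100,
                                          seed = 2))
  expect_error(sample_posterior(panel, spec), "zero-variance")
})
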