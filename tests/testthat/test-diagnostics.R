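test_that("psrf reproduces the Gelman-Rubin formula", {
  # chains (1,2,3) and (2,3,4): W = 1, B = 1.5, PSRF = sqrt(7/6)
  expect_equal(psrf(cbind(c(1, 2, 3), c(2, 3, 4))), sqrt(7 / 6))
  expect_equal(psrf(list(c(1, 2, 3), c(2, 3, 4))), sqrt(7 / 6))
  # duplicated chain: B = 0, PSRF = sqrt((n-1)/n) < 1
  x <- rnorm(50)
  expect_equal(psrf(cbind(x, x)), sqrt(49 / 50))
  # long chains from the same distribution approach 1
  set.seed(2)
  expect_equal(psrf(cbind(rnorm(20000), rnorm(20000))), 1, tolerance = 0.01)
  # degenerate: zero within-chain variance flags, does not crash
  expect_warning(out <- psrf(cbind(rep(1, 5), rep(2, 5))), "undefined")
  expect_true(is.na(out))
  expect_error(psrf(matrix(1:5, 5, 1)), "two chains")
})

test_that("accuracy discrepancy is the sum of squared Pearson residuals", {
  q <- q_matrix(matrix(1, 1, 1))
  # one cell, Y = 1, P = 0.5: 0.25 / 0.25 = 1
  expect_equal(
    discrepancy_ra(matrix(1), matrix(0), 0, q), 1.0
  )
  # Y == P pointwise gives zero
  theta <- matrix(qlogis(0.7))
  expect_equal(
    discrepancy_ra(matrix(0.7), theta, 0, q), 0
  )
  # expectation under the true model is about the number of observed cells
  set.seed(31)
  sim <- tiny_sim(N = 400, I = 6, seed = 31)
  d <- discrepancy_ra(
    sim$data$Y, sim$persons$theta, sim$items$d, sim$data$q
  )
  n_cells <- sum(sim$data$mask_y)
  expect_lt(abs(d - n_cells) / n_cells, 0.1)
  # typeset variant divides before squaring
  expect_equal(
    discrepancy_ra(matrix(1), matrix(0), 0, q, form = "typeset"),
    (0.5 / 0.25)^2
  )
})

test_that("time discrepancy is the sum of squared standardized errors", {
  q <- q_matrix(matrix(1, 1, 1))
  # one cell, omega = 2, residual 0.5: (2 * 0.5)^2 = 1
  expect_equal(
    discrepancy_rt(matrix(1.5), xi = 1.2, tau_tilde = matrix(0.2), omega = 2),
    1.0
  )
  expect_equal(
    discrepancy_rt(matrix(1.0), xi = 1.2, tau_tilde = matrix(0.2), omega = 2),
    0
  )
  expect_error(discrepancy_rt(matrix(1), 1, matrix(0), omega = -2), "positive")
  # chi-squared identity: mean about the number of observed cells
  sim <- tiny_sim(N = 400, I = 6, seed = 32)
  d <- discrepancy_rt(
    sim$data$logT, sim$items$xi, sim$persons$tau, sim$items$omega,
    q = sim$data$q
  )
  n_cells <- sum(sim$data$mask_t)
  expect_lt(abs(d - n_cells) / n_cells, 0.1)
})

test_that("ppp flags gross misfit and behaves sanely on its own data", {
  sim <- tiny_sim(N = 150, I = 6, seed = 14)
  f <- fit_mmj(sim$data, tiny_config(iter = 400, seed = 2))
  expect_warning(ppp(f, measure = "rt", n_draws = 50), "unstable")
  # data with times from a wildly wrong time-intensity: extreme ppp
  wrong <- sim$data
  wrong$logT <- wrong$logT + 3
  set.seed(5)
  p_bad <- ppp(f, data = wrong, measure = "rt", n_draws = 150)
  expect_lt(p_bad, 0.01)
  set.seed(6)
  p_ra <- ppp(f, measure = "ra", n_draws = 150)
  expect_gt(p_ra, 0.05)
  expect_lt(p_ra, 0.95)
})

test_that("ppp is spread over replications on well-specified data", {
  # calibration sanity: over independent replications the ppp values vary
  # and stay clear of the extremes (coarse Kolmogorov-type bound at n = 6)
  ps <- numeric(6)
  for (r in 1:6) {
    sim <- tiny_sim(N = 120, I = 6, seed = 40 + r)
    f <- fit_mmj(sim$data, tiny_config(iter = 300, seed = 50 + r))
    set.seed(60 + r)
    ps[r] <- ppp(f, measure = "ra", n_draws = 120)
  }
  expect_true(all(ps > 0.01 & ps < 0.99))
  expect_gt(max(ps) - min(ps), 0.02) # not degenerate
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate posterior gives zero WAIC penalty and -2 loglik", {
  q <- q_matrix(matrix(1, 1, 1))
  data <- joint_data(matrix(1), matrix(2.5), q)
  # a fit whose draws are all identical
  f <- fake_fit(list(c(0.3, 0.3), c(0.3, 0.3)))
  f$data <- data
  w <- waic(f, data, n_draws = 4)
  expect_equal(w$p_waic, 0)
  ll <- joint_loglik(
    data, person_params(matrix(0), matrix(0)), item_params(0.3, 4, 2)
  )$total
  expect_equal(w$waic, -2 * ll)
})

test_that("DIC effective parameters match the conjugate closed form", {
  # all blocks fixed except xi: a pure normal-normal model whose
  # effective number of parameters is the shrinkage weight per item
  sim <- tiny_sim(N = 80, I = 6, seed = 19)
  fixed <- list(
    theta = sim$persons$theta, tau = sim$persons$tau, d = sim$items$d,
    omega = sim$items$omega,
    sigma_person = person_covariance(sim$condition),
    mu_item = c(0, 4), sigma_item = diag(c(1, 0.25))
  )
  f <- fit_mmj(
    sim$data,
    sampler_config(n_chains = 2, n_iterations = 3000, n_burnin = 500, seed = 3),
    fixed = fixed
  )
  out <- dic(f)
  n <- colSums(sim$data$mask_t)
  om2 <- sim$items$omega^2
  p_expected <- sum((n * om2) / (n * om2 + 1 / 0.25))
  # Y-side likelihood is constant across draws here, so p_DIC counts only
  # the xi's; Monte-Carlo tolerance
  expect_equal(out$p_dic, p_expected, tolerance = 0.15)
})

test_that("information criteria prefer the matched speed structure", {
  sim <- tiny_sim(N = 200, I = 15, K = 3, rho = -0.7, seed = 23)
  cfg <- tiny_config(iter = 600, seed = 8)
  fmmj <- fit_mmj(sim$data, cfg)
  fmsj <- fit_msj(sim$data, cfg)
  expect_lt(dic(fmmj)$dic, dic(fmsj)$dic)
  expect_lt(waic(fmmj, n_draws = 150)$waic, waic(fmsj, n_draws = 150)$waic)
  # and the mismatch is not fatal to the sampler: chains still converge
  expect_lt(mmjoint:::max_psrf(fmsj), 1.2)
})
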