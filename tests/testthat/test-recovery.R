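test_that("bias and rmse follow their defining formulas", {
  expect_equal(bias(c(1, 2), 0), 1.5)
  expect_equal(rmse(c(1, 2), 0), sqrt(2.5))
  expect_equal(bias(rep(3, 5), 3), 0)
  expect_equal(rmse(rep(3, 5), 3), 0)
  expect_error(bias(numeric(0), 1), "no estimates")
  expect_error(rmse(numeric(0), 1), "no estimates")
  # decomposition: RMSE^2 = bias^2 + population variance (constant truth)
  set.seed(3)
  est <- rnorm(500, 1, 2)
  v <- mean((est - mean(est))^2)
  expect_equal(rmse(est, 0)^2, bias(est, 0)^2 + v)
})

test_that("correlation metric flags constant truth instead of failing", {
  expect_true(is.na(cor_metric(c(1.9, 2.1, 2.0), rep(2, 3))))
  expect_equal(cor_metric(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(1, 2, 3) - 2
  expect_equal(cor_metric(-x, x), -1)
  expect_error(cor_metric(1, 1), "two entities")
})

test_that("the full factorial design has 16 conditions", {
  design <- study_design(n_replications = 2, seed = 7)
  expect_length(design, 16)
  grid <- t(sapply(design, function(cc) {
    c(cc$N, cc$I, cc$K, cc$rho_theta_tau)
  }))
  expect_equal(nrow(unique(grid)), 16)
  expect_setequal(unique(grid[, 1]), c(500, 1000))
  expect_setequal(unique(grid[, 2]), c(15, 30))
  expect_setequal(unique(grid[, 3]), c(3, 5))
  expect_setequal(unique(grid[, 4]), c(-0.4, -0.7))
})

test_that("a single-replication condition report equals its one score", {
  cond <- sim_condition(
    N = 80, I = 6, K = 3, rho_theta_tau = -0.4, n_replications = 1, seed = 44
  )
  cfg <- sampler_config(n_chains = 2, n_iterations = 300, n_burnin = 150)
  rep <- run_condition(cond, sampler = cfg)
  expect_s3_class(rep, "recovery_report")
  expect_identical(rep$n_replications, 1L)
  # aggregation over one replication is that replication
  expect_equal(rep$items$rmse, rep$per_rep[[1]]$items$rmse)
  expect_equal(rep$persons$cor, rep$per_rep[[1]]$persons$cor)
  # report shape mirrors the published item table: bias/RMSE/cor per family
  expect_identical(rep$items$family, c("d", "xi", "omega"))
  expect_identical(names(rep$items), c("family", "bias", "rmse", "cor"))
  expect_true(is.na(rep$items$cor[rep$items$family == "omega"]))
  expect_true(all(rep$items$rmse >= abs(rep$items$bias)))
  # scoring is reproducible: the same condition gives the same report
  rep2 <- run_condition(cond, sampler = cfg)
  expect_equal(rep$items, rep2$items)
  expect_equal(rep$hyper, rep2$hyper)
})

test_that("cross-fitting the single-factor model on multifactor data runs", {
  cond <- sim_condition(
    N = 100, I = 15, K = 3, rho_theta_tau = -0.7, n_replications = 1, seed = 45
  )
  cfg <- sampler_config(n_chains = 2, n_iterations = 300, n_burnin = 150)
  matched <- run_condition(cond, fit_model = "MMJ", sampler = cfg)
  crossed <- run_condition(cond, fit_model = "MSJ", sampler = cfg)
  expect_identical(crossed$fit_model, "MSJ")
  # ignoring the multifactor speed structure inflates the time residuals:
  # the pooled speed factor leaves the between-factor spread in the error
  # term, dragging the time-precision estimates well below truth
  rmse_omega <- function(r) r$items$rmse[r$items$family == "omega"]
  bias_omega <- function(r) r$items$bias[r$items$family == "omega"]
  expect_gt(rmse_omega(crossed), rmse_omega(matched))
  expect_lt(bias_omega(crossed), bias_omega(matched) - 0.1)
})
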