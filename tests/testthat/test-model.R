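test_that("instantaneous speed is the Q-weighted sum of speed factors", {
  expect_equal(instantaneous_speed(c(0.3, -0.2, 0.1), c(0, 1, 0)), -0.2)
  expect_equal(instantaneous_speed(0.5, 1), 0.5) # K = 1 collapses
  expect_equal(instantaneous_speed(c(0.3, -0.2), c(1, 1)), 0.1)
  expect_error(instantaneous_speed(c(1, 2), c(1, 0, 0)), "shape")
  # matrix form vectorizes over persons
  tau <- rbind(c(0.3, -0.2), c(0, 0.4))
  expect_equal(instantaneous_speed(tau, c(0, 1)), c(-0.2, 0.4))
})

test_that("mr_prob is the inverse-logit of the Rasch predictor", {
  expect_equal(mr_prob(c(0, 0, 0), 0, c(1, 0, 0)), 0.5)
  expect_equal(mr_prob(c(1.2, 0, 0), -0.5, c(1, 0, 0)), plogis(0.7))
  expect_equal(plogis(0.7), 0.66819, tolerance = 1e-5)
  # logistic symmetry: P(theta, d) + P(-theta, -d) = 1
  set.seed(4)
  for (r in 1:20) {
    th <- rnorm(3)
    d <- rnorm(1)
    qr <- as.numeric(1:3 == sample(3, 1))
    expect_equal(mr_prob(th, d, qr) + mr_prob(-th, -d, qr), 1)
    # strictly increasing in d and in the measured theta
    eps <- 0.01
    expect_gt(mr_prob(th, d + eps, qr), mr_prob(th, d, qr))
    expect_gt(mr_prob(th + eps * qr, d, qr), mr_prob(th, d, qr))
  }
})

test_that("log response-time density is the stated normal log-density", {
  # at the mode with omega = 2: log(2 / sqrt(2 pi))
  expect_equal(logrt_logdensity(1.3, 1.5, 0.2, 2), log(2 / sqrt(2 * pi)))
  expect_equal(log(2 / sqrt(2 * pi)), -0.22579, tolerance = 1e-5)
  # quadratic decay: half a standardized unit off the mode
  expect_equal(
    logrt_logdensity(1.8, 1.5, 0.2, 2),
    log(2 / sqrt(2 * pi)) - 0.5 * (2 * 0.5)^2
  )
  # normalizes over log_t
  total <- integrate(
    function(x) exp(logrt_logdensity(x, 1, 0.3, 2)), -Inf, Inf
  )$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(logrt_logdensity(1, 1, 0, -1), "positive")
})

test_that("joint log-likelihood adds term-by-term over observed cells", {
  q <- q_matrix(rbind(c(1, 0), c(0, 1)))
  Y <- rbind(c(1, 0), c(NA, 1))
  tt <- rbind(c(2.5, NA), c(1.2, 4)) # seconds
  data <- joint_data(Y, tt, q)
  persons <- person_params(
    theta = rbind(c(0.4, -0.1), c(0, 1)),
    tau = rbind(c(0.2, 0), c(-0.3, 0.5))
  )
  items <- item_params(d = c(-0.2, 0.5), xi = c(1.1, 1.6), omega = c(2, 1.5))
  ll <- joint_loglik(data, persons, items)
  # independent oracle: accumulate the primitive operations cell by cell
  expected <- 0
  for (n in 1:2) {
    for (i in 1:2) {
      p <- mr_prob(persons$theta[n, ], items$d[i], q[i, ])
      if (!is.na(Y[n, i])) {
        expected <- expected + ifelse(Y[n, i] == 1, log(p), log(1 - p))
      }
      if (!is.na(tt[n, i])) {
        expected <- expected + logrt_logdensity(
          log(tt[n, i]), items$xi[i],
          instantaneous_speed(persons$tau[n, ], q[i, ]), items$omega[i]
        )
      }
    }
  }
  expect_equal(ll$total, expected)
  expect_equal(sum(ll$cells), ll$total)
  # missing cells contribute exactly zero and shield the total from edits
  expect_equal(ll$cells[2, 1], logrt_logdensity(
    log(1.2), items$xi[1], instantaneous_speed(persons$tau[2, ], q[1, ]),
    items$omega[1]
  )) # Y missing there: only the time term
  Y2 <- Y
  Y2[2, 1] <- 0 # value behind the mask must not matter
  data2 <- joint_data(Y2, tt, q)
  data2$mask_y[2, 1] <- FALSE
  expect_equal(joint_loglik(data2, persons, items)$total, ll$total)
})

test_that("single response cell with P = 0.5 gives log(0.5)", {
  q <- q_matrix(matrix(1, 1, 1))
  data <- joint_data(matrix(1), matrix(NA_real_), q)
  ll <- joint_loglik(
    data, person_params(matrix(0), matrix(0)),
    item_params(0, 4, 2)
  )
  expect_equal(ll$total, log(0.5))
})

test_that("all-missing data warn and give zero log-likelihood", {
  q <- q_matrix(matrix(1, 1, 1))
  data <- joint_data(matrix(NA), matrix(NA_real_), q)
  expect_warning(
    ll <- joint_loglik(
      data, person_params(matrix(0), matrix(0)), item_params(0, 4, 2)
    ),
    "no observed"
  )
  expect_equal(ll$total, 0)
})

test_that("multifactor density reduces exactly to the single-factor one at K = 1", {
  # MLRT with a one-column Q of ones is the SLRT: identical log-density
  set.seed(11)
  for (r in 1:10) {
    logt <- rnorm(1, 1.4, 0.6)
    xi <- rnorm(1, 4)
    tau <- rnorm(1, 0, 0.5)
    om <- runif(1, 0.5, 3)
    multi <- logrt_logdensity(logt, xi, instantaneous_speed(tau, 1), om)
    single <- dnorm(logt, xi - tau, 1 / om, log = TRUE)
    expect_identical(multi, single)
  }
})

test_that("joint log-likelihood is invariant to relabeling dimensions", {
  sim <- tiny_sim(N = 20, I = 6, K = 3, seed = 5)
  perm <- c(3, 1, 2)
  q2 <- q_matrix(unclass(sim$data$q)[, perm])
  data2 <- joint_data(sim$data$Y, exp(sim$data$logT), q2)
  persons2 <- person_params(
    sim$persons$theta[, perm], sim$persons$tau[, perm]
  )
  expect_equal(
    joint_loglik(sim$data, sim$persons, sim$items)$total,
    joint_loglik(data2, persons2, sim$items)$total
  )
})

test_that("population structure enforces positive definiteness and zero person mean", {
  ps <- population_structure(diag(4), mu_item = c(0, 4), sigma_item = diag(2))
  expect_identical(ps$mu_person, rep(0, 4))
  bad <- diag(4)
  bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(population_structure(bad), "positive definite")
  expect_error(
    population_structure(matrix(c(1, 2, 3, 4), 2)), "symmetric"
  )
  expect_error(item_params(0, 4, 0), "positive")
})
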