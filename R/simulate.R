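#' Simulation condition
#'
#' Bundles the generating quantities of one cell of the factorial
#' simulation design. The defaults are the study conditions of the
#' recovery simulations: abilities with unit variance and covariance 0.8,
#' speed factors with variance 0.25 and covariance 0.15 (correlation 0.6),
#' a constant ability-speed cross covariance of `0.5 * rho_theta_tau`,
#' item easiness/time-intensity drawn from a bivariate normal with mean
#' (0, 4) and covariance (1, -0.2; -0.2, 0.25) (so their correlation is
#' -0.4), and time precision omega = 2 for every item.
#'
#' @param N number of persons (500 or 1000 in the factorial design).
#' @param I number of items (15 or 30).
#' @param K number of ability dimensions (3 or 5).
#' @param rho_theta_tau correlation between an ability and a speed factor
#'   (-0.4 or -0.7).
#' @param rho_theta_theta correlation between two abilities.
#' @param rho_tau_tau correlation between two speed factors.
#' @param var_theta,var_tau ability / speed-factor variances.
#' @param item_mu length-2 mean (mu_d, mu_xi) of the item parameters.
#' @param item_cov 2 x 2 covariance of (d, xi).
#' @param omega_true generating time precision, shared by all items.
#' @param n_replications number of replications when the condition is run
#'   in a recovery study.
#' @param seed base seed for the condition.
#' @return An object of class `sim_condition`. The implied person
#'   covariance is checked for positive definiteness at construction.
#' @export
sim_condition <- function(N = 500, I = 15, K = 3, rho_theta_tau = -0.4,
                          rho_theta_theta = 0.8, rho_tau_tau = 0.6,
                          var_theta = 1, var_tau = 0.25,
                          item_mu = c(0, 4),
                          item_cov = matrix(c(1, -0.2, -0.2, 0.25), 2, 2),
                          omega_true = 2, n_replications = 30, seed = 1L) {
  stopifnot(N >= 1, I >= 1, K >= 1, var_theta > 0, var_tau > 0)
  cond <- structure(
    list(
      N = as.integer(N), I = as.integer(I), K = as.integer(K),
      rho_theta_tau = rho_theta_tau, rho_theta_theta = rho_theta_theta,
      rho_tau_tau = rho_tau_tau, var_theta = var_theta, var_tau = var_tau,
      item_mu = as.numeric(item_mu), item_cov = as.matrix(item_cov),
      omega_true = omega_true, n_replications = as.integer(n_replications),
      seed = as.integer(seed)
    ),
    class = "sim_condition"
  )
  check_pd(person_covariance(cond), "implied sigma_person")
  check_pd(cond$item_cov, "item_cov")
  cond
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "sim_condition: N = %d, I = %d, K = %d, rho_theta_tau = %.2f, R = %d\n",
    x$N, x$I, x$K, x$rho_theta_tau, x$n_replications
  ))
  invisible(x)
}

#' Person covariance implied by a simulation condition
#'
#' Builds the 2K x 2K covariance of (theta_1..theta_K, tau_1..tau_K): an
#' ability block with variance `var_theta` and common covariance, a speed
#' block with variance `var_tau` and common covariance, and a constant
#' cross block in which every theta-tau covariance equals
#' `0.5 * rho_theta_tau` (so with the default unit-ability and 0.25-speed
#' variances, every theta-tau correlation equals `rho_theta_tau`).
#'
#' @param condition a [sim_condition()].
#' @return A positive-definite 2K x 2K matrix.
#' @examples
#' person_covariance(sim_condition(K = 3, rho_theta_tau = -0.7))
#' @export
person_covariance <- function(condition) {
  stopifnot(inherits(condition, "sim_condition"))
  K <- condition$K
  theta_block <- matrix(
    condition$rho_theta_theta * condition$var_theta, K, K
  )
  diag(theta_block) <- condition$var_theta
  tau_block <- matrix(condition$rho_tau_tau * condition$var_tau, K, K)
  diag(tau_block) <- condition$var_tau
  # constant cross block: at the default variances (1 and 0.25) this is
  # 0.5 * rho_theta_tau in every cell, i.e. every theta-tau pair has
  # correlation rho_theta_tau
  cross <- matrix(
    condition$rho_theta_tau * sqrt(condition$var_theta * condition$var_tau),
    K, K
  )
  rbind(cbind(theta_block, cross), cbind(t(cross), tau_block))
}

# Cholesky-based MVN draws (mean 0), deterministic under set.seed().
# With exact = TRUE the sample is standardized so that its sample mean is
# exactly 0 and its sample covariance (n - 1 denominator) exactly sigma:
# the drawn parameters then realize the population moments they are meant
# to represent, so the identified zero person mean (and the generating
# hyperparameter values) hold in every replication, not just on average.
rmvn0 <- function(n, sigma, exact = FALSE) {
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (!exact) {
    return(z %*% chol(sigma))
  }
  if (n <= p) stop("moment-matched sampling needs more draws than dimensions")
  z <- sweep(z, 2, colMeans(z))
  z <- z %*% solve(chol(stats::cov(z)))
  z %*% chol(sigma)
}

#' Simulate a dataset from the joint generating process
#'
#' Draws person parameters from MVN(0, Sigma_person), item parameters
#' (d_i, xi_i) from the bivariate normal of the condition with
#' omega_i fixed at the condition's generating precision, then responses
#' `Y_ni ~ Bernoulli(mr_prob)` and times `log T_ni ~ N(xi_i - tau_tilde,
#' omega^-2)`; times are returned in seconds. Identical seeds give
#' bit-identical datasets.
#'
#' By default the drawn person and item parameter samples are standardized
#' to realize their population moments exactly (sample means and sample
#' covariances equal to the generating values in every replication). This
#' matches the identification constraint of the fitted model -- the person
#' means are fixed at zero -- inside each replication, so recovery errors
#' measure estimation error rather than the sampling fluctuation of the
#' drawn parameter sets; see the methods vignette. Set
#' `standardize_moments = FALSE` for plain i.i.d. draws.
#'
#' @param condition a [sim_condition()].
#' @param q optional [q_matrix()]; defaults to the balanced between-item
#'   blocks of the condition via [build_between_item_q()].
#' @param seed integer seed; defaults to the condition's seed.
#' @param gen_model `"MMJ"` (speed factors follow the Q-matrix) or `"MSJ"`
#'   (a single speed factor for all items; the person covariance is then
#'   (K+1) x (K+1) with the cross covariances of the single speed factor
#'   kept at the condition's constant cross value).
#' @param standardize_moments standardize the drawn parameter samples to
#'   their exact population moments (default TRUE; requires `N > 2K` and
#'   `I > 2`).
#' @return A list of class `mmj_sim` with `data` (a [joint_data()]),
#'   `persons`, `items`, `structure` (the generating
#'   [population_structure()]) and `condition`.
#' @export
simulate_mmj <- function(condition, q = NULL, seed = condition$seed,
                         gen_model = c("MMJ", "MSJ"),
                         standardize_moments = TRUE) {
  stopifnot(inherits(condition, "sim_condition"))
  gen_model <- match.arg(gen_model)
  if (is.null(q)) q <- build_between_item_q(condition$I, condition$K)
  stopifnot(nrow(q) == condition$I, ncol(q) == condition$K)
  set.seed(as.integer(seed))

  sigma_person <- person_covariance(condition)
  if (gen_model == "MSJ") {
    K <- condition$K
    keep <- c(seq_len(K), K + 1L)
    sigma_person <- sigma_person[keep, keep, drop = FALSE]
  }
  pp <- rmvn0(condition$N, sigma_person, exact = standardize_moments)
  Ka <- condition$K
  Ks <- ncol(sigma_person) - Ka
  theta <- pp[, seq_len(Ka), drop = FALSE]
  tau <- pp[, Ka + seq_len(Ks), drop = FALSE]

  it <- rmvn0(condition$I, condition$item_cov, exact = standardize_moments)
  d <- it[, 1] + condition$item_mu[1]
  xi <- it[, 2] + condition$item_mu[2]
  omega <- rep(condition$omega_true, condition$I)

  dd <- dim_of_item(q)
  ds <- if (Ks == 1) rep(1L, condition$I) else dd
  eta <- theta[, dd, drop = FALSE] + matrix(d, condition$N, condition$I, byrow = TRUE)
  Y <- matrix(
    stats::rbinom(length(eta), 1, stats::plogis(eta)),
    condition$N, condition$I
  )
  mu_logt <- matrix(xi, condition$N, condition$I, byrow = TRUE) -
    tau[, ds, drop = FALSE]
  logT <- mu_logt + matrix(
    stats::rnorm(length(mu_logt), sd = 1 / condition$omega_true),
    condition$N, condition$I
  )
  tt <- exp(logT)
  colnames(Y) <- colnames(tt) <- rownames(q)
  rownames(Y) <- rownames(tt) <- paste0("P", seq_len(condition$N))

  structure(
    list(
      data = joint_data(Y, tt, q),
      persons = person_params(theta, tau),
      items = item_params(d, xi, omega),
      structure = population_structure(
        sigma_person,
        mu_item = condition$item_mu, sigma_item = condition$item_cov
      ),
      condition = condition, seed = as.integer(seed), gen_model = gen_model
    ),
    class = "mmj_sim"
  )
}

#' @export
print.mmj_sim <- function(x, ...) {
  cat("simulated", x$gen_model, "dataset (seed", x$seed, ")\n")
  print(x$data)
  invisible(x)
}
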