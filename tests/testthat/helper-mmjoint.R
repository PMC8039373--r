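# Shared fixtures built in code.

# small joint dataset with a known Q-matrix; deterministic under seed
tiny_sim <- function(N = 60, I = 6, K = 3, rho = -0.4, seed = 1,
                     standardize = TRUE) {
  cond <- sim_condition(
    N = N, I = I, K = K, rho_theta_tau = rho, seed = seed
  )
  simulate_mmj(cond, standardize_moments = standardize)
}

# short two-chain sampler settings for unit tests
tiny_config <- function(iter = 400, seed = 1) {
  sampler_config(
    n_chains = 2, n_iterations = iter, n_burnin = iter %/% 2, seed = seed
  )
}

# hand-built minimal mmj_fit carrying prescribed draws for one item-level
# scalar chain; used to unit-test summaries without running the sampler
fake_fit <- function(d_chains) {
  n_kept <- length(d_chains[[1]])
  chains <- lapply(d_chains, function(dv) {
    list(
      theta = array(0, dim = c(1, 1, n_kept)),
      tau = array(0, dim = c(1, 1, n_kept)),
      d = matrix(dv, 1, n_kept),
      xi = matrix(4, 1, n_kept),
      omega = matrix(2, 1, n_kept),
      sigma_person = array(rep(diag(2), n_kept), dim = c(2, 2, n_kept)),
      mu_item = matrix(c(0, 4), 2, n_kept),
      sigma_item = array(rep(diag(2), n_kept), dim = c(2, 2, n_kept)),
      loglik = rep(0, n_kept), n_kept = n_kept
    )
  })
  structure(
    list(
      variant = "MMJ", chains = chains,
      config = suppressWarnings(sampler_config(
        n_chains = length(chains), n_iterations = 2 * n_kept,
        n_burnin = n_kept
      )),
      priors = prior_spec(), fixed = character(),
      dims = list(N = 1L, I = 1L, Ka = 1L, Ks = 1L),
      item_ids = "Item1", dim_ids = "Dim1"
    ),
    class = "mmj_fit"
  )
}
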