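#' Sampler configuration
#'
#' Chain protocol for the Gibbs sampler. The defaults mirror the study
#' protocol: two chains of 10,000 iterations each, the first 5,000
#' discarded as burn-in, no thinning.
#'
#' @param n_chains number of chains (at least 2 for PSRF diagnostics).
#' @param n_iterations iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2, n_iterations = 10000,
                           n_burnin = 5000, thinning = 1, seed = 1L) {
  stopifnot(n_chains >= 1, n_iterations > 0, thinning >= 1)
  if (n_burnin >= n_iterations) stop("n_burnin must be smaller than n_iterations")
  if (n_chains < 2) {
    warning("fewer than 2 chains: PSRF convergence checks will be unavailable")
  }
  structure(
    list(
      n_chains = as.integer(n_chains), n_iterations = as.integer(n_iterations),
      n_burnin = as.integer(n_burnin), thinning = as.integer(thinning),
      seed = as.integer(seed)
    ),
    class = "sampler_config"
  )
}

#' Prior specification
#'
#' Weakly informative priors of the hierarchical model. Person parameters
#' are MVN(0, Sigma_person) with Sigma_person inverse-Wishart (identity
#' scale, degrees of freedom equal to its dimension); item parameters are
#' bivariate normal with normal hyperpriors on (mu_d, mu_xi) and an
#' inverse-Wishart (identity scale, 2 df) hyperprior on Sigma_item; the
#' residual variance omega^-2 is InvGamma(1, 1).
#'
#' The second argument of the normal hyperpriors (`mu_d_spread`,
#' `mu_xi_spread`) is read on the scale named by `hyperprior_scale`:
#' `"variance"` (the default) or `"precision"`. See the methods vignette
#' for why variance is the default.
#'
#' @param mu_d_mean,mu_d_spread normal hyperprior on mu_d.
#' @param mu_xi_mean,mu_xi_spread normal hyperprior on mu_xi.
#' @param hyperprior_scale how to read the spread arguments.
#' @param omega_ig shape and rate of the InvGamma prior on omega^-2.
#' @param item_df inverse-Wishart degrees of freedom for Sigma_item.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_d_mean = 0, mu_d_spread = 2,
                       mu_xi_mean = 4.3, mu_xi_spread = 2,
                       hyperprior_scale = c("variance", "precision"),
                       omega_ig = c(1, 1), item_df = 2) {
  hyperprior_scale <- match.arg(hyperprior_scale)
  stopifnot(mu_d_spread > 0, mu_xi_spread > 0, all(omega_ig > 0), item_df >= 2)
  structure(
    list(
      mu_d_mean = mu_d_mean, mu_d_spread = mu_d_spread,
      mu_xi_mean = mu_xi_mean, mu_xi_spread = mu_xi_spread,
      hyperprior_scale = hyperprior_scale,
      omega_ig = omega_ig, item_df = item_df
    ),
    class = "prior_spec"
  )
}

hyper_precision <- function(spread, scale) {
  if (scale == "precision") spread else 1 / spread
}

#' Fit the joint model by MCMC
#'
#' `fit_mmj()` fits the full joint model: multidimensional Rasch for
#' accuracy, multifactor lognormal for times, with the speed factors
#' following the Q-matrix. `fit_msj()` replaces the speed structure with a
#' single factor shared by all items (the accuracy side stays
#' multidimensional). `fit_slrt()` fits the response-time-only
#' single-factor lognormal model (the accuracy likelihood is dropped).
#'
#' The sampler is a Gibbs scheme in which the logistic accuracy terms are
#' augmented with Polya-Gamma variables so every conditional is conjugate:
#' persons and items are drawn from multivariate normal conditionals,
#' omega^-2 from its inverse-gamma conditional, and the population
#' covariances from inverse-Wishart conditionals. The latent scales are
#' identified by fixing the person-level means at zero (they are never
#' sampled). Missing responses and missing times are skipped cell-wise in
#' every conditional.
#'
#' @param data a [joint_data()].
#' @param config a [sampler_config()].
#' @param priors a [prior_spec()].
#' @param fixed named list of blocks to hold fixed instead of sampling
#'   (any of `theta`, `tau`, `d`, `xi`, `omega`, `sigma_person`,
#'   `mu_item`, `sigma_item`); mainly for validation against closed-form
#'   or quadrature posteriors.
#' @param verbose print the joint log-likelihood every 500 iterations.
#' @return An object of class `mmj_fit` holding per-chain draws of all
#'   parameters, the configuration, priors and the data.
#' @export
fit_mmj <- function(data, config = sampler_config(), priors = prior_spec(),
                    fixed = list(), verbose = FALSE) {
  fit_joint(data, "MMJ", config, priors, fixed, verbose)
}

#' @rdname fit_mmj
#' @export
fit_msj <- function(data, config = sampler_config(), priors = prior_spec(),
                    fixed = list(), verbose = FALSE) {
  fit_joint(data, "MSJ", config, priors, fixed, verbose)
}

#' @rdname fit_mmj
#' @export
fit_slrt <- function(data, config = sampler_config(), priors = prior_spec(),
                     fixed = list(), verbose = FALSE) {
  fit_joint(data, "SLRT", config, priors, fixed, verbose)
}

fit_joint <- function(data, variant, config, priors, fixed, verbose) {
  stopifnot(inherits(data, "joint_data"), inherits(config, "sampler_config"),
    inherits(priors, "prior_spec"))
  allowed <- c(
    "theta", "tau", "d", "xi", "omega", "sigma_person", "mu_item",
    "sigma_item"
  )
  if (length(fixed) && !all(names(fixed) %in% allowed)) {
    stop(
      "unknown fixed block(s): ",
      paste(setdiff(names(fixed), allowed), collapse = ", ")
    )
  }
  N <- nrow(data$Y)
  I <- ncol(data$Y)
  K <- ncol(data$q)
  use_y <- variant != "SLRT"
  Ka <- if (use_y) K else 0L
  Ks <- if (variant == "MMJ") K else 1L
  Kstar <- Ka + Ks
  dd <- dim_of_item(data$q) - 1L
  ds <- if (Ks == 1) rep(0L, I) else dd

  Ymat <- data$Y
  Ymat[!data$mask_y] <- 0L
  storage.mode(Ymat) <- "integer"
  logT <- data$logT
  logT[!data$mask_t] <- 0

  prec_mu_d <- hyper_precision(priors$mu_d_spread, priors$hyperprior_scale)
  prec_mu_xi <- hyper_precision(priors$mu_xi_spread, priors$hyperprior_scale)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    init <- chain_init(data, N, I, Ka, Ks, priors)
    chains[[ch]] <- .gibbs_chain(
      Ymat, logT, data$mask_y * 1L, data$mask_t * 1L, dd, ds, Ka, Ks, use_y,
      config$n_iterations, config$n_burnin, config$thinning,
      diag(Kstar), Kstar, diag(2), priors$item_df,
      priors$mu_d_mean, prec_mu_d, priors$mu_xi_mean, prec_mu_xi,
      priors$omega_ig[1], priors$omega_ig[2],
      init, fixed, verbose, 500L
    )
  }
  structure(
    list(
      variant = variant, chains = chains, config = config, priors = priors,
      fixed = names(fixed), data = data,
      dims = list(N = N, I = I, Ka = Ka, Ks = Ks),
      item_ids = rownames(data$q), dim_ids = colnames(data$q)
    ),
    class = "mmj_fit"
  )
}

# Random starting points for one chain: person and item parameters drawn
# around their prior centers, hyperparameters at weakly dispersed values.
# Called after set.seed(), so starts are reproducible per chain.
chain_init <- function(data, N, I, Ka, Ks, priors) {
  obs_mean <- if (any(data$mask_t)) mean(data$logT[data$mask_t]) else priors$mu_xi_mean
  list(
    theta = matrix(stats::rnorm(N * Ka), N, Ka),
    tau = matrix(stats::rnorm(N * Ks, sd = 0.5), N, Ks),
    d = stats::rnorm(I),
    xi = stats::rnorm(I, mean = obs_mean, sd = 0.5),
    sig2 = rep(1, I),
    sigma_person = diag(c(rep(1, Ka), rep(0.5, Ks)), Ka + Ks),
    mu_item = c(
      stats::rnorm(1, priors$mu_d_mean, 0.5),
      stats::rnorm(1, obs_mean, 0.5)
    ),
    sigma_item = diag(c(1, 0.5))
  )
}

#' @export
print.mmj_fit <- function(x, ...) {
  n_kept <- x$chains[[1]]$n_kept
  cat(sprintf(
    "%s fit: %d persons x %d items (K_ability = %d, K_speed = %d)\n",
    x$variant, x$dims$N, x$dims$I, x$dims$Ka, x$dims$Ks
  ))
  cat(sprintf(
    "  %d chain(s) x %d kept draws (of %d iterations, %d burn-in, thin %d)\n",
    length(x$chains), n_kept, x$config$n_iterations, x$config$n_burnin,
    x$config$thinning
  ))
  if (length(x$fixed)) cat("  fixed blocks:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior means of all parameter blocks
#'
#' Pools the post-burn-in draws of all chains and returns the posterior
#' mean of each parameter block, the point estimates of the model.
#'
#' @param fit an `mmj_fit`.
#' @return A list with `theta` (N x Ka, absent for the time-only variant),
#'   `tau` (N x Ks), `d`, `xi`, `omega` (length I), `sigma_person`,
#'   `mu_item`, `sigma_item`.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "mmj_fit"))
  avg_over_chains <- function(name) {
    a <- Reduce(`+`, lapply(fit$chains, function(ch) {
      x <- ch[[name]]
      apply(x, seq_len(length(dim(x)) - 1L), mean)
    }))
    a / length(fit$chains)
  }
  out <- list(
    tau = avg_over_chains("tau"),
    d = drop(avg_over_chains("d")),
    xi = drop(avg_over_chains("xi")),
    omega = drop(avg_over_chains("omega")),
    sigma_person = avg_over_chains("sigma_person"),
    mu_item = drop(avg_over_chains("mu_item")),
    sigma_item = avg_over_chains("sigma_item")
  )
  if (fit$dims$Ka > 0) out$theta <- avg_over_chains("theta")
  out
}

# iterate over scalar parameter names and their per-chain draw matrices
# (draws x chains); person blocks are included only when `persons = TRUE`
# (they dominate the parameter count).
flatten_draws <- function(fit, persons = TRUE) {
  n_kept <- fit$chains[[1]]$n_kept
  blocks <- list()
  grab <- function(name) {
    lapply(fit$chains, function(ch) ch[[name]])
  }
  add_matrix_block <- function(name, labels) {
    xs <- grab(name) # I x D matrices
    for (j in seq_along(labels)) {
      blocks[[labels[j]]] <<- sapply(xs, function(m) m[j, ])
    }
  }
  add_cube_block <- function(name, rowlab, collab) {
    xs <- grab(name) # R x C x D cubes
    for (cc in seq_along(collab)) {
      for (rr in seq_along(rowlab)) {
        lab <- paste0(name, "[", rowlab[rr], ",", collab[cc], "]")
        blocks[[lab]] <<- sapply(xs, function(a) a[rr, cc, ])
      }
    }
  }
  I <- fit$dims$I
  add_matrix_block("d", paste0("d[", seq_len(I), "]"))
  add_matrix_block("xi", paste0("xi[", seq_len(I), "]"))
  add_matrix_block("omega", paste0("omega[", seq_len(I), "]"))
  xs <- grab("mu_item")
  blocks[["mu_d"]] <- sapply(xs, function(m) m[1, ])
  blocks[["mu_xi"]] <- sapply(xs, function(m) m[2, ])
  Kstar <- fit$dims$Ka + fit$dims$Ks
  sp <- grab("sigma_person")
  for (a in seq_len(Kstar)) {
    for (b in a:Kstar) {
      blocks[[paste0("sigma_person[", a, ",", b, "]")]] <-
        sapply(sp, function(x) x[a, b, ])
    }
  }
  si <- grab("sigma_item")
  for (a in 1:2) {
    for (b in a:2) {
      blocks[[paste0("sigma_item[", a, ",", b, "]")]] <-
        sapply(si, function(x) x[a, b, ])
    }
  }
  if (persons) {
    if (fit$dims$Ka > 0) {
      th <- grab("theta")
      for (k in seq_len(fit$dims$Ka)) {
        for (n in seq_len(fit$dims$N)) {
          blocks[[paste0("theta[", n, ",", k, "]")]] <-
            sapply(th, function(a) a[n, k, ])
        }
      }
    }
    ta <- grab("tau")
    for (k in seq_len(fit$dims$Ks)) {
      for (n in seq_len(fit$dims$N)) {
        blocks[[paste0("tau[", n, ",", k, "]")]] <-
          sapply(ta, function(a) a[n, k, ])
      }
    }
  }
  lapply(blocks, function(m) matrix(m, nrow = n_kept))
}

#' Posterior summary table
#'
#' Posterior mean (the point estimate), posterior SD, central 95% credible
#' interval and, with at least two chains, the potential scale reduction
#' factor for each scalar parameter.
#'
#' @param fit an `mmj_fit`.
#' @param persons include the per-person ability and speed parameters
#'   (default TRUE; they dominate the table for large N).
#' @return A data.frame with one row per scalar parameter, invariant to
#'   chain order.
#' @export
posterior_summary <- function(fit, persons = TRUE) {
  stopifnot(inherits(fit, "mmj_fit"))
  blocks <- flatten_draws(fit, persons = persons)
  multi <- length(fit$chains) >= 2
  rows <- lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    pooled <- as.vector(m)
    data.frame(
      parameter = nm,
      mean = mean(pooled),
      sd = stats::sd(pooled),
      lower95 = unname(stats::quantile(pooled, 0.025)),
      upper95 = unname(stats::quantile(pooled, 0.975)),
      psrf = if (multi) psrf(m) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
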