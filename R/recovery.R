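#' Recovery metrics: bias, RMSE, correlation
#'
#' `bias()` is the mean of `estimates - truth`; `rmse()` the root mean
#' square of the same differences; `cor_metric()` the Pearson correlation
#' of estimates with truth across entities (items or persons) within one
#' replication, returning `NA` when the truth is constant (as for a
#' generating time precision shared by all items) instead of failing.
#'
#' @param estimates numeric vector of estimates (per replication, or per
#'   entity for `cor_metric`).
#' @param truth numeric vector or scalar of true values.
#' @return A scalar; `cor_metric()` may return `NA_real_`.
#' @examples
#' bias(c(1, 2), 0) # 1.5
#' rmse(c(1, 2), 0) # sqrt(2.5)
#' cor_metric(c(1.9, 2.1, 2), rep(2, 3)) # NA: constant truth
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates supplied")
  mean(estimates - truth)
}

#' @rdname bias
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates supplied")
  sqrt(mean((estimates - truth)^2))
}

#' @rdname bias
#' @export
cor_metric <- function(estimates, truth) {
  if (length(estimates) < 2) stop("correlation needs at least two entities")
  if (length(truth) == 1) truth <- rep(truth, length(estimates))
  if (stats::sd(truth) == 0) {
    return(NA_real_)
  }
  stats::cor(estimates, truth)
}

# Fast maximum PSRF over every scalar parameter of a fit (including all
# person parameters), via per-chain moment matrices rather than flattening.
max_psrf <- function(fit) {
  if (length(fit$chains) < 2) {
    return(NA_real_)
  }
  n <- fit$chains[[1]]$n_kept
  worst <- 1
  for (name in c(
    "theta", "tau", "d", "xi", "omega", "sigma_person", "mu_item",
    "sigma_item"
  )) {
    mats <- lapply(fit$chains, function(ch) {
      x <- ch[[name]]
      d <- dim(x)
      matrix(x, prod(d[-length(d)]), d[length(d)])
    })
    if (nrow(mats[[1]]) == 0) next
    means <- sapply(mats, rowMeans)
    vars <- sapply(mats, function(m) {
      rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
    })
    w <- rowMeans(vars)
    b_over_n <- apply(means, 1, stats::var)
    ok <- w > 0
    if (!any(ok)) next
    r <- sqrt(((n - 1) / n * w[ok] + b_over_n[ok]) / w[ok])
    worst <- max(worst, r)
  }
  worst
}

# realized population moments of one simulated replication, the reference
# values against which hyperparameter estimates are scored (see vignette)
realized_moments <- function(sim) {
  pp <- cbind(sim$persons$theta, sim$persons$tau)
  list(
    mu_d = mean(sim$items$d),
    mu_xi = mean(sim$items$xi),
    sigma_item = stats::cov(cbind(sim$items$d, sim$items$xi)),
    sigma_person = stats::cov(pp)
  )
}

#' Run one recovery condition: simulate, fit, score
#'
#' For each replication, a dataset is simulated from `gen_model` under the
#' condition (replication `r` uses seed `condition$seed + r`), the
#' `fit_model` is fitted by MCMC, convergence is checked (PSRF of every
#' parameter below 1.2; violations are recorded, not fatal), and posterior
#' means are scored against the truth: bias, RMSE and within-replication
#' correlation for item and person parameters, and bias/RMSE of the
#' population-level parameters against the realized sample moments of the
#' generated parameters (see the methods vignette for this scoring
#' convention).
#'
#' @param condition a [sim_condition()].
#' @param fit_model,gen_model `"MMJ"` or `"MSJ"`.
#' @param sampler a [sampler_config()]; its seed is ignored (replication
#'   seeds are derived from the condition seed).
#' @param n_replications number of replications; defaults to the
#'   condition's.
#' @return An object of class `recovery_report` with aggregate tables
#'   (`items`, `persons`, `hyper`), the per-replication raw metrics
#'   (`per_rep`), and convergence bookkeeping.
#' @export
run_condition <- function(condition, fit_model = c("MMJ", "MSJ"),
                          gen_model = c("MMJ", "MSJ"),
                          sampler = sampler_config(
                            n_chains = 2, n_iterations = 3000,
                            n_burnin = 1500
                          ),
                          n_replications = condition$n_replications) {
  fit_model <- match.arg(fit_model)
  gen_model <- match.arg(gen_model)
  stopifnot(inherits(condition, "sim_condition"), n_replications >= 1)
  K <- condition$K
  Ks_fit <- if (fit_model == "MMJ") K else 1L
  per_rep <- vector("list", n_replications)
  failures <- 0L

  for (r in seq_len(n_replications)) {
    seed_r <- condition$seed + r
    sim <- simulate_mmj(condition, seed = seed_r, gen_model = gen_model)
    cfg <- sampler_config(
      n_chains = sampler$n_chains, n_iterations = sampler$n_iterations,
      n_burnin = sampler$n_burnin, thinning = sampler$thinning,
      seed = seed_r + 500000L
    )
    fit <- tryCatch(
      if (fit_model == "MMJ") fit_mmj(sim$data, cfg) else fit_msj(sim$data, cfg),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning("replication ", r, " aborted: ", conditionMessage(fit))
      failures <- failures + 1L
      next
    }
    pm <- posterior_means(fit)
    mom <- realized_moments(sim)
    mp <- max_psrf(fit)

    item_tab <- data.frame(
      family = c("d", "xi", "omega"),
      bias = c(
        bias(pm$d, sim$items$d), bias(pm$xi, sim$items$xi),
        bias(pm$omega, sim$items$omega)
      ),
      rmse = c(
        rmse(pm$d, sim$items$d), rmse(pm$xi, sim$items$xi),
        rmse(pm$omega, sim$items$omega)
      ),
      cor = c(
        cor_metric(pm$d, sim$items$d), cor_metric(pm$xi, sim$items$xi),
        cor_metric(pm$omega, sim$items$omega)
      )
    )

    theta_tab <- do.call(rbind, lapply(seq_len(K), function(k) {
      data.frame(
        family = paste0("theta", k),
        bias = bias(pm$theta[, k], sim$persons$theta[, k]),
        rmse = rmse(pm$theta[, k], sim$persons$theta[, k]),
        cor = cor_metric(pm$theta[, k], sim$persons$theta[, k])
      )
    }))
    # speed factors comparable only when the fitted and generating speed
    # structures agree in dimension
    tau_tab <- NULL
    if (Ks_fit == ncol(sim$persons$tau)) {
      tau_tab <- do.call(rbind, lapply(seq_len(Ks_fit), function(k) {
        data.frame(
          family = paste0("tau", k),
          bias = bias(pm$tau[, k], sim$persons$tau[, k]),
          rmse = rmse(pm$tau[, k], sim$persons$tau[, k]),
          cor = cor_metric(pm$tau[, k], sim$persons$tau[, k])
        )
      }))
    } else if (Ks_fit == 1) {
      # single fitted factor scored against each generating factor's items
      # is not defined; score against the person mean speed instead
      avg <- rowMeans(sim$persons$tau)
      tau_tab <- data.frame(
        family = "tau1",
        bias = bias(pm$tau[, 1], avg), rmse = rmse(pm$tau[, 1], avg),
        cor = cor_metric(pm$tau[, 1], avg)
      )
    }

    sp <- pm$sigma_person
    hyper_err <- c(
      mu_d = pm$mu_item[1] - mom$mu_d,
      mu_xi = pm$mu_item[2] - mom$mu_xi,
      sigma_d2 = pm$sigma_item[1, 1] - mom$sigma_item[1, 1],
      sigma_dxi = pm$sigma_item[1, 2] - mom$sigma_item[1, 2],
      sigma_xi2 = pm$sigma_item[2, 2] - mom$sigma_item[2, 2]
    )
    if (fit_model == gen_model) {
      Kstar <- K + Ks_fit
      vlab <- c(paste0("sigma_theta", seq_len(K), "2"),
        paste0("sigma_tau", seq_len(Ks_fit), "2"))
      verr <- diag(sp) - diag(mom$sigma_person)[seq_len(Kstar)]
      names(verr) <- vlab
      hyper_err <- c(hyper_err, verr)
    }

    per_rep[[r]] <- list(
      items = item_tab, persons = rbind(theta_tab, tau_tab),
      hyper_err = hyper_err, max_psrf = mp,
      converged = is.finite(mp) && mp < 1.2, seed = seed_r
    )
  }

  done <- !vapply(per_rep, is.null, logical(1))
  if (!any(done)) stop("all replications failed")
  reps <- per_rep[done]

  agg <- function(field) {
    tabs <- lapply(reps, `[[`, field)
    base <- tabs[[1]][, "family", drop = FALSE]
    for (m in c("bias", "rmse", "cor")) {
      base[[m]] <- rowMeans(sapply(tabs, `[[`, m))
    }
    base
  }
  errs <- t(sapply(reps, `[[`, "hyper_err"))
  hyper <- data.frame(
    family = colnames(errs),
    bias = colMeans(errs),
    rmse = sqrt(colMeans(errs^2)),
    row.names = NULL
  )

  structure(
    list(
      condition = condition, fit_model = fit_model, gen_model = gen_model,
      n_replications = sum(done), n_failed = failures,
      items = agg("items"), persons = agg("persons"), hyper = hyper,
      max_psrf = max(vapply(reps, `[[`, numeric(1), "max_psrf")),
      n_nonconverged = sum(!vapply(reps, `[[`, logical(1), "converged")),
      per_rep = reps, complete = failures == 0L
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery: gen %s / fit %s, N = %d, I = %d, K = %d, rho = %.1f, R = %d\n",
    x$gen_model, x$fit_model, x$condition$N, x$condition$I, x$condition$K,
    x$condition$rho_theta_tau, x$n_replications
  ))
  if (x$n_failed > 0) cat("  INCOMPLETE:", x$n_failed, "replication(s) failed\n")
  cat(sprintf(
    "  max PSRF %.3f (%d replication(s) above 1.2)\n",
    x$max_psrf, x$n_nonconverged
  ))
  cat("items:\n")
  print(x$items, digits = 3)
  cat("persons:\n")
  print(x$persons, digits = 3)
  cat("population parameters (vs realized moments):\n")
  print(x$hyper, digits = 3)
  invisible(x)
}

#' The full factorial simulation design
#'
#' The 2 x 2 x 2 x 2 grid of the recovery study: N in (500, 1000), I in
#' (15, 30), ability-speed correlation in (-0.4, -0.7), K in (3, 5).
#'
#' @param n_replications replications per condition (30 in the full study).
#' @param seed base seed; condition `j` gets `seed + 1000 * j`.
#' @return A list of 16 [sim_condition()] objects.
#' @export
study_design <- function(n_replications = 30, seed = 1L) {
  grid <- expand.grid(
    N = c(500L, 1000L), I = c(15L, 30L),
    rho = c(-0.4, -0.7), K = c(3L, 5L)
  )
  lapply(seq_len(nrow(grid)), function(j) {
    sim_condition(
      N = grid$N[j], I = grid$I[j], K = grid$K[j],
      rho_theta_tau = grid$rho[j],
      n_replications = n_replications, seed = seed + 1000L * j
    )
  })
}

#' Run a recovery study over a design grid
#'
#' Maps [run_condition()] over a list of conditions and stacks the
#' aggregate tables, one row per condition and parameter family, shaped
#' like the published recovery tables. Deterministic given the condition
#' seeds.
#'
#' @param design list of [sim_condition()]s, e.g. [study_design()].
#' @param fit_model,gen_model model variants, as in [run_condition()].
#' @param sampler a [sampler_config()] template.
#' @param out_dir optional directory; when given, `items.csv`,
#'   `persons.csv`, `hyper.csv` and a JSON summary are written there.
#' @return A list with `reports` (per condition) and stacked data.frames
#'   `items`, `persons`, `hyper`.
#' @export
run_study <- function(design, fit_model = "MMJ", gen_model = "MMJ",
                      sampler = sampler_config(
                        n_chains = 2, n_iterations = 3000, n_burnin = 1500
                      ),
                      out_dir = NULL) {
  reports <- lapply(design, function(cond) {
    run_condition(cond, fit_model, gen_model, sampler = sampler)
  })
  stack <- function(field) {
    do.call(rbind, lapply(reports, function(rep) {
      cond <- rep$condition
      cbind(
        data.frame(
          I = cond$I, N = cond$N, rho_theta_tau = cond$rho_theta_tau,
          K = cond$K
        ),
        rep[[field]]
      )
    }))
  }
  out <- list(
    reports = reports, items = stack("items"), persons = stack("persons"),
    hyper = stack("hyper")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$items, file.path(out_dir, "items.csv"), row.names = FALSE)
    utils::write.csv(out$persons, file.path(out_dir, "persons.csv"), row.names = FALSE)
    utils::write.csv(out$hyper, file.path(out_dir, "hyper.csv"), row.names = FALSE)
    summary <- lapply(reports, function(rep) {
      list(
        N = rep$condition$N, I = rep$condition$I, K = rep$condition$K,
        rho_theta_tau = rep$condition$rho_theta_tau,
        n_replications = rep$n_replications, max_psrf = rep$max_psrf,
        n_nonconverged = rep$n_nonconverged
      )
    })
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}
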