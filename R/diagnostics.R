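#' Potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic for one scalar parameter tracked by
#' several chains: `sqrt((((n - 1) / n) * W + B / n) / W)` with `W` the
#' mean within-chain variance and `B` the between-chain variance of the
#' chain means times `n`. Values near 1 indicate convergence; values below
#' 1.2 are taken as converged in the recovery studies.
#'
#' @param x a draws-by-chains numeric matrix, or a list of equal-length
#'   numeric vectors (one per chain).
#' @return The PSRF, or `NA` (with a warning) when every chain has zero
#'   within-chain variance.
#' @examples
#' psrf(cbind(c(1, 2, 3), c(2, 3, 4))) # sqrt(7/6)
#' @export
psrf <- function(x) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) stop("chains must have equal lengths")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop("PSRF needs at least two chains")
  if (n < 2) stop("PSRF needs at least two draws per chain")
  w <- mean(apply(x, 2, stats::var))
  if (w == 0) {
    warning("zero within-chain variance in all chains; PSRF undefined")
    return(NA_real_)
  }
  b <- n * stats::var(colMeans(x))
  sqrt((((n - 1) / n) * w + b / n) / w)
}

#' Response-accuracy discrepancy: sum of squared Pearson residuals
#'
#' `sum over observed cells of (Y - P)^2 / (P (1 - P))` with `P` the
#' correct-response probability of the multidimensional Rasch model at the
#' supplied parameters. `form = "typeset"` gives the variant in which the
#' residual is divided by `P (1 - P)` before squaring.
#'
#' @param Y N x I binary response matrix (NA allowed).
#' @param theta N x K ability matrix.
#' @param d length-I easiness vector.
#' @param q a [q_matrix()].
#' @param mask optional N x I logical observed-indicator; defaults to
#'   `!is.na(Y)`.
#' @param form `"pearson"` (default) or `"typeset"`.
#' @return The scalar discrepancy.
#' @export
discrepancy_ra <- function(Y, theta, d, q, mask = NULL,
                           form = c("pearson", "typeset")) {
  form <- match.arg(form)
  Y <- as.matrix(Y)
  theta <- as.matrix(theta)
  if (is.null(mask)) mask <- !is.na(Y)
  dd <- dim_of_item(q)
  P <- stats::plogis(theta[, dd, drop = FALSE] +
    matrix(d, nrow(Y), ncol(Y), byrow = TRUE))
  res <- (Y - P)
  contrib <- if (form == "pearson") {
    res^2 / (P * (1 - P))
  } else {
    (res / (P * (1 - P)))^2
  }
  sum(contrib[mask])
}

#' Response-time discrepancy: sum of squared standardized errors
#'
#' `sum over observed cells of (omega_i (logT - (xi_i - tau_tilde)))^2`.
#'
#' @param logT N x I matrix of log response times (NA allowed).
#' @param xi length-I time-intensity vector.
#' @param tau_tilde N x I matrix of instantaneous speeds (or an N x K
#'   speed-factor matrix together with `q`).
#' @param omega length-I positive precision vector.
#' @param q optional [q_matrix()]; required when `tau_tilde` is a factor
#'   matrix rather than already item-expanded.
#' @param mask optional observed-indicator; defaults to `!is.na(logT)`.
#' @return The scalar discrepancy.
#' @export
discrepancy_rt <- function(logT, xi, tau_tilde, omega, q = NULL, mask = NULL) {
  if (any(omega <= 0)) stop("omega must be strictly positive")
  logT <- as.matrix(logT)
  if (is.null(mask)) mask <- !is.na(logT)
  tau_tilde <- as.matrix(tau_tilde)
  if (!all(dim(tau_tilde) == dim(logT))) {
    if (is.null(q)) stop("supply q to expand speed factors to items")
    ds <- if (ncol(tau_tilde) == 1) rep(1L, ncol(logT)) else dim_of_item(q)
    tau_tilde <- tau_tilde[, ds, drop = FALSE]
  }
  mu <- matrix(xi, nrow(logT), ncol(logT), byrow = TRUE) - tau_tilde
  z <- matrix(omega, nrow(logT), ncol(logT), byrow = TRUE) * (logT - mu)
  sum((z[mask])^2)
}

# Map a pooled draw index to one chain/draw state of the fit.
draw_state <- function(fit, j) {
  n_kept <- fit$chains[[1]]$n_kept
  ch <- ((j - 1) %/% n_kept) + 1L
  ix <- ((j - 1) %% n_kept) + 1L
  c_ <- fit$chains[[ch]]
  list(
    theta = if (fit$dims$Ka > 0) {
      matrix(c_$theta[, , ix], fit$dims$N, fit$dims$Ka)
    },
    tau = matrix(c_$tau[, , ix], fit$dims$N, fit$dims$Ks),
    d = c_$d[, ix], xi = c_$xi[, ix], omega = c_$omega[, ix]
  )
}

pooled_draw_indices <- function(fit, n_draws) {
  total <- fit$chains[[1]]$n_kept * length(fit$chains)
  unique(round(seq(1, total, length.out = min(n_draws, total))))
}

#' Posterior predictive p-value
#'
#' Posterior predictive model checking with one of the two discrepancy
#' measures: for `n_draws` (roughly evenly spaced) posterior draws, data
#' are replicated from the model at that draw, the discrepancy of the
#' replicated and the observed data are both evaluated at the same draw,
#' and the fraction of draws with `D(rep) >= D(obs)` is returned. Values
#' near 0.5 indicate no systematic difference between model and data;
#' values near 0 or 1 indicate misfit.
#'
#' @param fit an `mmj_fit`.
#' @param data a [joint_data()]; defaults to the data the model was
#'   fitted to.
#' @param measure `"ra"` (accuracy, squared Pearson residuals) or `"rt"`
#'   (times, squared standardized errors).
#' @param n_draws number of posterior draws used (default 500; fewer than
#'   100 triggers a warning).
#' @return The ppp value in `[0, 1]`.
#' @export
ppp <- function(fit, data = fit$data, measure = c("ra", "rt"), n_draws = 500) {
  stopifnot(inherits(fit, "mmj_fit"))
  measure <- match.arg(measure)
  if (measure == "ra" && fit$dims$Ka == 0) {
    stop("the time-only variant has no accuracy side to check")
  }
  if (n_draws < 100) warning("fewer than 100 draws gives an unstable ppp estimate")
  idx <- pooled_draw_indices(fit, n_draws)
  N <- fit$dims$N
  I <- fit$dims$I
  dd <- dim_of_item(data$q)
  ds <- if (fit$dims$Ks == 1) rep(1L, I) else dd
  exceed <- logical(length(idx))
  for (j in seq_along(idx)) {
    st <- draw_state(fit, idx[j])
    if (measure == "ra") {
      P <- stats::plogis(st$theta[, dd, drop = FALSE] +
        matrix(st$d, N, I, byrow = TRUE))
      d_obs <- sum(((data$Y - P)^2 / (P * (1 - P)))[data$mask_y])
      yrep <- matrix(stats::rbinom(N * I, 1, P), N, I)
      d_rep <- sum(((yrep - P)^2 / (P * (1 - P)))[data$mask_y])
    } else {
      mu <- matrix(st$xi, N, I, byrow = TRUE) - st$tau[, ds, drop = FALSE]
      om <- matrix(st$omega, N, I, byrow = TRUE)
      d_obs <- sum((om * (data$logT - mu))[data$mask_t]^2)
      zrep <- matrix(stats::rnorm(N * I), N, I)
      d_rep <- sum((zrep[data$mask_t])^2)
    }
    exceed[j] <- d_rep >= d_obs
  }
  mean(exceed)
}

# Per-cell log-likelihood components for a set of pooled draws:
# draws x cells matrix over the observed (response or time) cells.
pointwise_loglik <- function(fit, data, idx) {
  obs <- data$mask_y | data$mask_t
  keep <- which(obs)
  out <- matrix(NA_real_, length(idx), length(keep))
  for (j in seq_along(idx)) {
    st <- draw_state(fit, idx[j])
    persons <- person_params(
      theta = if (fit$dims$Ka > 0) st$theta else matrix(0, fit$dims$N, 0),
      tau = st$tau
    )
    items <- item_params(st$d, st$xi, st$omega)
    ll <- joint_loglik_cells(data, persons, items, use_y = fit$dims$Ka > 0)
    out[j, ] <- ll[keep]
  }
  out
}

# cells matrix shared by WAIC/DIC and the time-only variant (which has no
# accuracy term even when responses are present in the dataset)
joint_loglik_cells <- function(data, persons, items, use_y = TRUE) {
  N <- nrow(data$Y)
  I <- ncol(data$Y)
  dd <- dim_of_item(data$q)
  ds <- if (ncol(persons$tau) == 1) rep(1L, I) else dd
  cells <- matrix(0, N, I)
  if (use_y) {
    P <- stats::plogis(persons$theta[, dd, drop = FALSE] +
      matrix(items$d, N, I, byrow = TRUE))
    ly <- ifelse(data$Y == 1, log(P), log1p(-P))
    cells[data$mask_y] <- cells[data$mask_y] + ly[data$mask_y]
  }
  mu <- matrix(items$xi, N, I, byrow = TRUE) - persons$tau[, ds, drop = FALSE]
  om <- matrix(items$omega, N, I, byrow = TRUE)
  lt <- stats::dnorm(data$logT, mu, 1 / om, log = TRUE)
  cells[data$mask_t] <- cells[data$mask_t] + lt[data$mask_t]
  cells
}

#' Deviance information criterion
#'
#' `DIC = -2 log p(y | posterior-mean parameters) + 2 p_DIC` with
#' `p_DIC = 2 (log p at the posterior means - mean of log p over draws)`.
#' The plug-in uses the posterior means of all parameters, including the
#' person parameters; the likelihood is the joint one over observed
#' responses and log times. Smaller is better.
#'
#' @param fit an `mmj_fit`.
#' @param data a [joint_data()]; defaults to the fitted data.
#' @return A list with `dic`, `p_dic`, and the plug-in deviance `d_hat`.
#' @export
dic <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "mmj_fit"))
  mean_ll <- mean(unlist(lapply(fit$chains, function(ch) ch$loglik)))
  pm <- posterior_means(fit)
  persons <- person_params(
    theta = if (fit$dims$Ka > 0) pm$theta else matrix(0, fit$dims$N, 0),
    tau = matrix(pm$tau, fit$dims$N, fit$dims$Ks)
  )
  items <- item_params(pm$d, pm$xi, pm$omega)
  ll_hat <- sum(joint_loglik_cells(data, persons, items, use_y = fit$dims$Ka > 0))
  if (!is.finite(ll_hat) || !is.finite(mean_ll)) {
    stop("non-finite log-likelihood in DIC computation")
  }
  p_dic <- 2 * (ll_hat - mean_ll)
  list(dic = -2 * ll_hat + 2 * p_dic, p_dic = p_dic, d_hat = -2 * ll_hat)
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_WAIC)` over per-cell points, where a point is the
#' person-item cell combining its response term and its time term when
#' both are observed. The penalty is the variance form: `p_WAIC =
#' sum over cells of var(log p)` across posterior draws. Smaller is
#' better.
#'
#' @param fit an `mmj_fit`.
#' @param data a [joint_data()]; defaults to the fitted data.
#' @param n_draws number of posterior draws used for the pointwise
#'   computation (default 500).
#' @return A list with `waic`, `p_waic`, `lppd`.
#' @export
waic <- function(fit, data = fit$data, n_draws = 500) {
  stopifnot(inherits(fit, "mmj_fit"))
  idx <- pooled_draw_indices(fit, n_draws)
  ll <- pointwise_loglik(fit, data, idx)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)
    stop("non-finite pointwise log-likelihood (first at cell ", bad[1, 2], ")")
  }
  s <- nrow(ll)
  # column-wise log-sum-exp
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Model fit report
#'
#' Bundles the fit diagnostics of one fitted model: both ppp values, DIC,
#' WAIC and the per-parameter PSRF table.
#'
#' @param fit an `mmj_fit`.
#' @param n_draws posterior draws for ppp and WAIC.
#' @param persons include person parameters in the PSRF table.
#' @return A list of class `fit_report` with `ppp_ra`, `ppp_rt`, `dic`,
#'   `waic`, `psrf` (named vector), `max_psrf`.
#' @export
fit_report <- function(fit, n_draws = 500, persons = TRUE) {
  stopifnot(inherits(fit, "mmj_fit"))
  summ <- posterior_summary(fit, persons = persons)
  ps <- stats::setNames(summ$psrf, summ$parameter)
  structure(
    list(
      ppp_ra = if (fit$dims$Ka > 0) ppp(fit, measure = "ra", n_draws = n_draws) else NA_real_,
      ppp_rt = ppp(fit, measure = "rt", n_draws = n_draws),
      dic = dic(fit)$dic,
      waic = waic(fit, n_draws = n_draws)$waic,
      psrf = ps,
      max_psrf = suppressWarnings(max(ps, na.rm = TRUE))
    ),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "fit report: DIC %.1f  WAIC %.1f  ppp_RA %s  ppp_RT %.3f  max PSRF %.3f\n",
    x$dic, x$waic,
    if (is.na(x$ppp_ra)) "NA" else sprintf("%.3f", x$ppp_ra),
    x$ppp_rt, x$max_psrf
  ))
  invisible(x)
}
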