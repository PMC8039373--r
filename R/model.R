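#' Person parameters
#'
#' Container for the latent person parameters of the joint model: abilities
#' `theta` (logit scale) and working-speed factors `tau` (log-time scale),
#' one column per dimension.
#'
#' @param theta N x K numeric matrix of abilities.
#' @param tau N x K numeric matrix of speed factors. For the
#'   single-factor-speed variant `tau` may have a single column.
#' @return An object of class `person_params`.
#' @export
person_params <- function(theta, tau) {
  theta <- as.matrix(theta)
  tau <- as.matrix(tau)
  if (nrow(theta) != nrow(tau)) stop("theta and tau must describe the same persons")
  if (!all(is.finite(theta)) || !all(is.finite(tau))) stop("person parameters must be finite")
  structure(list(theta = theta, tau = tau), class = "person_params")
}

#' Item parameters
#'
#' Container for the item parameters: easiness `d` (logit scale),
#' time-intensity `xi` (log-seconds) and time-precision `omega`, the
#' reciprocal of the residual SD of log response time. All interfaces work
#' with `omega` itself, never its square.
#'
#' @param d length-I numeric vector of easiness parameters.
#' @param xi length-I numeric vector of time intensities.
#' @param omega length-I positive vector of time precisions.
#' @return An object of class `item_params`.
#' @export
item_params <- function(d, xi, omega) {
  if (length(d) != length(xi) || length(d) != length(omega)) {
    stop("d, xi and omega must have one entry per item")
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be strictly positive")
  structure(list(d = as.numeric(d), xi = as.numeric(xi), omega = as.numeric(omega)),
    class = "item_params"
  )
}

#' Population structure of the joint model
#'
#' The person parameters (theta_1..theta_K, tau_1..tau_K) follow a
#' multivariate normal with mean zero (fixed, for identification of the
#' latent scales) and covariance `sigma_person`; the item parameters
#' (d_i, xi_i) follow a bivariate normal with mean `mu_item` and covariance
#' `sigma_item`.
#'
#' @param sigma_person 2K x 2K (or (K+1) x (K+1) for single-factor speed)
#'   symmetric positive-definite covariance of the person parameters,
#'   ordered theta first, tau second.
#' @param mu_item length-2 vector (mu_d, mu_xi).
#' @param sigma_item 2 x 2 symmetric positive-definite item covariance.
#' @return An object of class `population_structure` with a zero
#'   `mu_person` field.
#' @export
population_structure <- function(sigma_person, mu_item = c(0, 4), sigma_item = diag(2)) {
  sigma_person <- as.matrix(sigma_person)
  sigma_item <- as.matrix(sigma_item)
  check_pd(sigma_person, "sigma_person")
  check_pd(sigma_item, "sigma_item")
  stopifnot(length(mu_item) == 2, all(dim(sigma_item) == 2))
  structure(
    list(
      sigma_person = sigma_person,
      mu_person = rep(0, nrow(sigma_person)),
      mu_item = as.numeric(mu_item),
      sigma_item = sigma_item
    ),
    class = "population_structure"
  )
}

check_pd <- function(m, name) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop(name, " must be symmetric")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(name, " is not positive definite (smallest eigenvalue ", signif(min(ev), 4), ")")
  }
  invisible(TRUE)
}

#' Paired response / response-time dataset
#'
#' Binds a binary response matrix `Y`, a positive response-time matrix `tt`
#' (seconds) and a [q_matrix()] into one dataset. Missingness is tracked
#' per cell and independently for responses and times (an observed response
#' may have a missing time, as when zero recorded times are discarded).
#' Times that are zero or negative are coerced to missing; the number of
#' coerced cells is kept in the `n_coerced_times` attribute.
#'
#' @param Y N x I matrix over 0/1/NA.
#' @param tt N x I matrix of response times in seconds (NA allowed).
#' @param q a [q_matrix()] with `I` rows.
#' @return An object of class `joint_data` with fields `Y`, `logT`,
#'   `mask_y`, `mask_t`, `q`.
#' @export
joint_data <- function(Y, tt, q) {
  stopifnot(inherits(q, "qmatrix"))
  Y <- as.matrix(Y)
  tt <- as.matrix(tt)
  if (!all(dim(Y) == dim(tt))) stop("Y and tt must have the same shape")
  if (ncol(Y) != nrow(q)) {
    stop("dataset has ", ncol(Y), " items but the Q-matrix has ", nrow(q))
  }
  bad_y <- Y[!is.na(Y) & !(Y %in% c(0, 1))]
  if (length(bad_y)) {
    idx <- which(!is.na(Y) & !(Y %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop(
      "responses must be 0/1/NA; found ", bad_y[1], " at person ", idx[1],
      ", item ", idx[2]
    )
  }
  storage.mode(Y) <- "integer"
  n_coerced <- sum(!is.na(tt) & tt <= 0)
  tt[!is.na(tt) & tt <= 0] <- NA
  mask_y <- !is.na(Y)
  mask_t <- !is.na(tt)
  logT <- matrix(NA_real_, nrow(tt), ncol(tt), dimnames = dimnames(tt))
  logT[mask_t] <- log(tt[mask_t])
  structure(
    list(
      Y = Y, logT = logT, mask_y = mask_y, mask_t = mask_t, q = q,
      n_coerced_times = n_coerced
    ),
    class = "joint_data"
  )
}

#' @export
print.joint_data <- function(x, ...) {
  cat(
    "joint_data:", nrow(x$Y), "persons x", ncol(x$Y), "items,",
    ncol(x$q), "dimensions\n"
  )
  cat(
    "  observed responses:", sum(x$mask_y), " observed times:",
    sum(x$mask_t)
  )
  if (x$n_coerced_times > 0) {
    cat("  (", x$n_coerced_times, "non-positive times coerced to missing )")
  }
  cat("\n")
  invisible(x)
}

#' Instantaneous speed at an item
#'
#' The speed a person applies to an item is the Q-weighted sum of their
#' speed factors, `sum_k tau_k q_k`; with one-hot rows this selects the
#' factor of the item's dimension.
#'
#' @param tau length-K speed vector, or an N x K matrix of speed factors.
#' @param q_row length-K binary loading vector for one item.
#' @return A scalar (or length-N vector when `tau` is a matrix).
#' @examples
#' instantaneous_speed(c(0.3, -0.2, 0.1), c(0, 1, 0))
#' @export
instantaneous_speed <- function(tau, q_row) {
  if (is.matrix(tau)) {
    if (ncol(tau) != length(q_row)) stop("tau and q_row shapes do not match")
    return(drop(tau %*% q_row))
  }
  if (length(tau) != length(q_row)) stop("tau and q_row shapes do not match")
  sum(tau * q_row)
}

#' Correct-response probability under the multidimensional Rasch model
#'
#' `P(Y = 1) = logit^-1(sum_k theta_k q_k + d)`, strictly inside (0, 1).
#'
#' @param theta length-K ability vector, or an N x K matrix.
#' @param d item easiness (scalar).
#' @param q_row length-K binary loading vector for the item.
#' @return Probability scalar (or length-N vector).
#' @examples
#' mr_prob(c(1.2, 0, 0), -0.5, c(1, 0, 0))
#' @export
mr_prob <- function(theta, d, q_row) {
  eta <- instantaneous_speed(theta, q_row) + d
  stats::plogis(eta)
}

#' Log-density of a log response time
#'
#' Under the multifactor lognormal model, `log T ~ N(xi - tau_tilde,
#' omega^-2)`; this evaluates the normal log-density of an observed
#' `log_t`. Natural logarithms are used throughout.
#'
#' @param log_t observed log response time(s).
#' @param xi item time-intensity.
#' @param tau_tilde instantaneous speed of the person at this item.
#' @param omega time precision (> 0), the reciprocal residual SD.
#' @return Log-density value(s).
#' @export
logrt_logdensity <- function(log_t, xi, tau_tilde, omega) {
  if (any(omega <= 0)) stop("omega must be strictly positive")
  stats::dnorm(log_t, mean = xi - tau_tilde, sd = 1 / omega, log = TRUE)
}

#' Joint log-likelihood of a dataset
#'
#' Sums the Bernoulli log-mass of observed responses and the lognormal
#' (evaluated on the log scale) log-density of observed times, under local
#' independence of the two given the person and item parameters. Missing
#' cells contribute exactly zero. The per-cell components (response term
#' plus time term per person-item cell) are returned for pointwise use in
#' WAIC and DIC.
#'
#' @param data a [joint_data()].
#' @param persons a [person_params()].
#' @param items an [item_params()].
#' @return A list with `total` (scalar log-likelihood) and `cells`
#'   (N x I matrix of per-cell contributions; 0 where nothing is observed).
#' @export
joint_loglik <- function(data, persons, items) {
  stopifnot(inherits(data, "joint_data"))
  dd <- dim_of_item(data$q)
  N <- nrow(data$Y)
  I <- ncol(data$Y)
  if (nrow(persons$theta) != N) stop("persons do not match the dataset")
  if (length(items$d) != I) stop("items do not match the dataset")
  cells <- matrix(0, N, I)
  for (i in seq_len(I)) {
    k <- dd[i]
    oy <- data$mask_y[, i]
    if (any(oy)) {
      p <- mr_prob(persons$theta[oy, , drop = FALSE], items$d[i], data$q[i, ])
      cells[oy, i] <- cells[oy, i] +
        ifelse(data$Y[oy, i] == 1, log(p), log1p(-p))
    }
    ot <- data$mask_t[, i]
    if (any(ot)) {
      tt <- instantaneous_speed(persons$tau[ot, , drop = FALSE], qrow_speed(data$q, persons, i))
      cells[ot, i] <- cells[ot, i] +
        logrt_logdensity(data$logT[ot, i], items$xi[i], tt, items$omega[i])
    }
  }
  total <- sum(cells)
  if (sum(data$mask_y) + sum(data$mask_t) == 0) {
    warning("dataset has no observed cells; log-likelihood is 0")
  }
  list(total = total, cells = cells)
}

# Speed loading row for item i: the Q row itself when the speed structure is
# multifactor, or all-ones collapsed to the single factor when persons carry
# one speed column (single-factor-speed variant).
qrow_speed <- function(q, persons, i) {
  if (ncol(persons$tau) == ncol(q)) {
    q[i, ]
  } else if (ncol(persons$tau) == 1) {
    1
  } else {
    stop("tau has ", ncol(persons$tau), " columns; expected ", ncol(q), " or 1")
  }
}
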