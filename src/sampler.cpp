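// Gibbs sampler for the joint model of multidimensional ability and
// multifactor working speed.
//
// Accuracy: logit P(Y_ni = 1) = theta_{n,a(i)} + d_i   (between-item Q:
// each item loads one ability dimension a(i) and one speed factor s(i)).
// Times:    log T_ni ~ N(xi_i - tau_{n,s(i)}, sig2_i),  sig2_i = omega_i^-2.
// Persons:  (theta_n, tau_n) ~ MVN(0, Sigma_person).
// Items:    (d_i, xi_i) ~ MVN(mu_item, Sigma_item), sig2_i ~ InvGamma(a0, b0).
//
// The logistic terms are handled by Polya-Gamma augmentation (exact
// alternating-series sampler for PG(1, z)); every conditional is then
// conjugate, so the chain has no Metropolis step. All randomness comes
// from R's RNG: set.seed() on the R side makes a chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TRUNC_PG = 0.64;  // left/right split point for PG(1, z)

// ---- Polya-Gamma PG(1, z) ------------------------------------------------

// Piecewise coefficients of the alternating series for the Jacobi-type
// density targeted by the accept/reject step.
static double pg_acoef(int n, double x) {
  double dn = n + 0.5;
  if (x > TRUNC_PG)
    return M_PI * dn * std::exp(-dn * dn * M_PI * M_PI * 0.5 * x);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * dn *
         std::exp(-2.0 * dn * dn / x);
}

// Probability that the proposal is drawn from the exponential right tail
// (rather than the truncated inverse-Gaussian left piece).
static double pg_right_mass(double z) {
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / TRUNC_PG) * (TRUNC_PG * z - 1.0);
  double a = -std::sqrt(1.0 / TRUNC_PG) * (TRUNC_PG * z + 1.0);
  double x0 = std::log(fz) + fz * TRUNC_PG;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC_PG].
static double pg_rtigauss(double z) {
  double x = TRUNC_PG + 1.0;
  if (z < 1.0 / TRUNC_PG) {  // rejection from scaled chi-like proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC_PG);
      x = TRUNC_PG / ((1.0 + TRUNC_PG * e1) * (1.0 + TRUNC_PG * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {  // draw IG, reject until inside the interval
    double mu = 1.0 / z;
    while (x > TRUNC_PG) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// Exact draw from PG(1, z) by the alternating-series method.
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  for (;;) {
    double x;
    if (unif_rand() < pg_right_mass(z))
      x = TRUNC_PG + exp_rand() / fz;
    else
      x = pg_rtigauss(z);
    double s = pg_acoef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_acoef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_acoef(n, x);
        if (y > s) break;
      }
    }
  }
}

// ---- multivariate normal / Wishart helpers (R RNG) -----------------------

static arma::vec mvn_from_precision(const arma::mat& lambda,
                                    const arma::vec& lin) {
  arma::mat u = arma::chol(lambda);  // lambda = u' u
  arma::vec m =
      arma::solve(arma::trimatu(u), arma::solve(arma::trimatl(u.t()), lin));
  arma::vec z(lin.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return m + arma::solve(arma::trimatu(u), z);
}

static arma::mat rwishart(double nu, const arma::mat& scale) {
  int p = scale.n_rows;
  arma::mat l = arma::chol(scale, "lower");
  arma::mat a(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) a(i, i) = std::sqrt(R::rchisq(nu - i));
  for (int i = 1; i < p; ++i)
    for (int j = 0; j < i; ++j) a(i, j) = norm_rand();
  arma::mat la = l * a;
  return la * la.t();
}

static arma::mat rinvwishart(double nu, const arma::mat& psi) {
  return arma::inv_sympd(rwishart(nu, arma::inv_sympd(psi)));
}

// ---- joint log-likelihood of the current state (for logging/sanity) ------

static double state_loglik(const arma::imat& Y, const arma::mat& logT,
                           const arma::umat& maskY, const arma::umat& maskT,
                           const arma::uvec& dima, const arma::uvec& dims,
                           const arma::mat& theta, const arma::mat& tau,
                           const arma::vec& d, const arma::vec& xi,
                           const arma::vec& sig2, bool use_y) {
  double ll = 0.0;
  int N = logT.n_rows, I = logT.n_cols;
  for (int i = 0; i < I; ++i) {
    double om2 = 1.0 / sig2(i);
    double lhalf = -0.5 * std::log(2.0 * M_PI * sig2(i));
    for (int n = 0; n < N; ++n) {
      if (use_y && maskY(n, i)) {
        double eta = theta(n, dima(i)) + d(i);
        // log Bernoulli mass via log1p(exp(.)) for stability
        double lp = -std::log1p(std::exp(-eta));
        double lq = -std::log1p(std::exp(eta));
        ll += Y(n, i) == 1 ? lp : lq;
      }
      if (maskT(n, i)) {
        double r = logT(n, i) - (xi(i) - tau(n, dims(i)));
        ll += lhalf - 0.5 * r * r * om2;
      }
    }
  }
  return ll;
}

// ---- main chain ----------------------------------------------------------

// [[Rcpp::export(".gibbs_chain")]]
List gibbs_chain(const arma::imat& Y, const arma::mat& logT,
                 const arma::umat& maskY, const arma::umat& maskT,
                 const arma::uvec& dima, const arma::uvec& dims, int Ka,
                 int Ks, bool use_y, int n_iter, int n_burnin, int thin,
                 const arma::mat& r_person, double df_person,
                 const arma::mat& r_item, double df_item, double mu_d0,
                 double prec_mu_d, double mu_xi0, double prec_mu_xi,
                 double ig_shape, double ig_rate, List init, List fixed,
                 bool verbose, int report_every) {
  int N = logT.n_rows, I = logT.n_cols;
  int Kstar = Ka + Ks;

  // state
  arma::mat theta = as<arma::mat>(init["theta"]);  // N x Ka (0 cols if !use_y)
  arma::mat tau = as<arma::mat>(init["tau"]);      // N x Ks
  arma::vec d = as<arma::vec>(init["d"]);
  arma::vec xi = as<arma::vec>(init["xi"]);
  arma::vec sig2 = as<arma::vec>(init["sig2"]);
  arma::mat sigma_person = as<arma::mat>(init["sigma_person"]);
  arma::vec mu_item = as<arma::vec>(init["mu_item"]);
  arma::mat sigma_item = as<arma::mat>(init["sigma_item"]);

  bool fix_theta = fixed.containsElementNamed("theta");
  bool fix_tau = fixed.containsElementNamed("tau");
  bool fix_d = fixed.containsElementNamed("d");
  bool fix_xi = fixed.containsElementNamed("xi");
  bool fix_sig2 = fixed.containsElementNamed("omega");
  bool fix_sp = fixed.containsElementNamed("sigma_person");
  bool fix_mu = fixed.containsElementNamed("mu_item");
  bool fix_si = fixed.containsElementNamed("sigma_item");
  if (fix_theta) theta = as<arma::mat>(fixed["theta"]);
  if (fix_tau) tau = as<arma::mat>(fixed["tau"]);
  if (fix_d) d = as<arma::vec>(fixed["d"]);
  if (fix_xi) xi = as<arma::vec>(fixed["xi"]);
  if (fix_sig2) {
    arma::vec om = as<arma::vec>(fixed["omega"]);
    sig2 = 1.0 / arma::square(om);
  }
  if (fix_sp) sigma_person = as<arma::mat>(fixed["sigma_person"]);
  if (fix_mu) mu_item = as<arma::vec>(fixed["mu_item"]);
  if (fix_si) sigma_item = as<arma::mat>(fixed["sigma_item"]);

  // free/fixed index sets for the block-partitioned conditionals
  std::vector<arma::uword> pf, pc;  // person: free / fixed coordinates
  for (int k = 0; k < Ka; ++k) (fix_theta ? pc : pf).push_back(k);
  for (int k = 0; k < Ks; ++k) (fix_tau ? pc : pf).push_back(Ka + k);
  arma::uvec person_free(pf), person_fix(pc);
  std::vector<arma::uword> itf, itc;  // item: d = 0, xi = 1
  (fix_d ? itc : itf).push_back(0);
  (fix_xi ? itc : itf).push_back(1);
  arma::uvec item_free(itf), item_fix(itc);

  int n_keep = (n_iter - n_burnin) / thin;
  arma::cube theta_draws(N, Ka, use_y ? n_keep : 0);
  arma::cube tau_draws(N, Ks, n_keep);
  arma::mat d_draws(I, n_keep), xi_draws(I, n_keep), omega_draws(I, n_keep);
  arma::cube sp_draws(Kstar, Kstar, n_keep);
  arma::mat mu_item_draws(2, n_keep);
  arma::cube si_draws(2, 2, n_keep);
  arma::vec loglik_draws(n_keep);

  arma::mat w(N, I, arma::fill::zeros);  // Polya-Gamma auxiliaries
  int keep = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();

    arma::mat p_person = arma::inv_sympd(sigma_person);
    arma::mat p_item = arma::inv_sympd(sigma_item);
    arma::vec om2 = 1.0 / sig2;

    // -- Polya-Gamma auxiliaries + person-level sufficient statistics
    arma::mat acc_prec(N, Kstar, arma::fill::zeros);
    arma::mat acc_lin(N, Kstar, arma::fill::zeros);
    arma::vec sw(I, arma::fill::zeros), swt(I, arma::fill::zeros);
    arma::vec st(I, arma::fill::zeros), nT(I, arma::fill::zeros);
    for (int i = 0; i < I; ++i) {
      int ka = use_y ? (int)dima(i) : 0;
      int ks = Ka + (int)dims(i);
      for (int n = 0; n < N; ++n) {
        if (use_y && maskY(n, i)) {
          double eta = theta(n, ka) + d(i);
          double wni = rpg1(eta);
          w(n, i) = wni;
          double kappa = Y(n, i) - 0.5;
          acc_prec(n, ka) += wni;
          acc_lin(n, ka) += kappa - wni * d(i);
          sw(i) += wni;
          swt(i) += kappa - wni * theta(n, ka);
        }
        if (maskT(n, i)) {
          acc_prec(n, ks) += om2(i);
          acc_lin(n, ks) += om2(i) * (xi(i) - logT(n, i));
          nT(i) += 1.0;
          st(i) += logT(n, i) + tau(n, dims(i));
        }
      }
    }

    // -- persons: (theta_n, tau_n) | rest is MVN (prior mean 0)
    if (person_free.n_elem > 0) {
      arma::mat pff = p_person(person_free, person_free);
      arma::mat pfc = person_fix.n_elem
                          ? arma::mat(p_person(person_free, person_fix))
                          : arma::mat(person_free.n_elem, 0);
      for (int n = 0; n < N; ++n) {
        arma::mat lambda = pff;
        arma::vec lin(person_free.n_elem);
        for (arma::uword j = 0; j < person_free.n_elem; ++j) {
          lambda(j, j) += acc_prec(n, person_free(j));
          lin(j) = acc_lin(n, person_free(j));
        }
        if (person_fix.n_elem) {
          arma::vec xc(person_fix.n_elem);
          for (arma::uword j = 0; j < person_fix.n_elem; ++j) {
            arma::uword c = person_fix(j);
            xc(j) = c < (arma::uword)Ka ? theta(n, c) : tau(n, c - Ka);
          }
          lin -= pfc * xc;
        }
        arma::vec draw = mvn_from_precision(lambda, lin);
        for (arma::uword j = 0; j < person_free.n_elem; ++j) {
          arma::uword k = person_free(j);
          if (k < (arma::uword)Ka)
            theta(n, k) = draw(j);
          else
            tau(n, k - Ka) = draw(j);
        }
      }
    }

    // recompute xi-side statistic with the fresh tau draws
    if (person_free.n_elem > 0 && !fix_xi) {
      st.zeros();
      for (int i = 0; i < I; ++i)
        for (int n = 0; n < N; ++n)
          if (maskT(n, i)) st(i) += logT(n, i) + tau(n, dims(i));
    }

    // -- items: (d_i, xi_i) | rest is bivariate normal
    if (item_free.n_elem > 0) {
      arma::vec pmu = p_item * mu_item;
      for (int i = 0; i < I; ++i) {
        // refresh the d-side statistic with current theta
        if (use_y && !fix_d) {
          swt(i) = 0.0;
          int ka = (int)dima(i);
          for (int n = 0; n < N; ++n)
            if (maskY(n, i))
              swt(i) += (Y(n, i) - 0.5) - w(n, i) * theta(n, ka);
        }
        arma::vec likp(2), likl(2);
        likp(0) = use_y ? sw(i) : 0.0;
        likl(0) = use_y ? swt(i) : 0.0;
        likp(1) = nT(i) * om2(i);
        likl(1) = om2(i) * st(i);
        arma::mat lambda = p_item(item_free, item_free);
        arma::vec lin(item_free.n_elem);
        for (arma::uword j = 0; j < item_free.n_elem; ++j) {
          lambda(j, j) += likp(item_free(j));
          lin(j) = pmu(item_free(j)) + likl(item_free(j));
        }
        if (item_fix.n_elem) {
          arma::vec xc(item_fix.n_elem);
          for (arma::uword j = 0; j < item_fix.n_elem; ++j)
            xc(j) = item_fix(j) == 0 ? d(i) : xi(i);
          lin -= p_item(item_free, item_fix) * xc;
        }
        arma::vec draw = mvn_from_precision(lambda, lin);
        for (arma::uword j = 0; j < item_free.n_elem; ++j) {
          if (item_free(j) == 0)
            d(i) = draw(j);
          else
            xi(i) = draw(j);
        }
      }
    }

    // -- translation moves along the likelihood-invariant directions.
    // Shifting every theta_{nk} by delta and subtracting delta from d_i of
    // that dimension's items leaves the Rasch predictor unchanged (and
    // likewise tau_{nk} / xi_i for the time side), so these directions are
    // pinned only by the priors and mix slowly under blockwise updates.
    // Their full conditionals are Gaussian; sampling them exactly each
    // iteration restores fast mixing (a group move, exact Gibbs).
    {
      arma::vec psum = arma::zeros(Kstar);
      if (Ka > 0) psum.subvec(0, Ka - 1) = arma::sum(theta, 0).t();
      psum.subvec(Ka, Kstar - 1) = arma::sum(tau, 0).t();
      arma::vec pp_all = p_person * psum;
      p_item = arma::inv_sympd(sigma_item);
      if (use_y && !fix_theta && !fix_d) {
        for (int k = 0; k < Ka; ++k) {
          arma::vec s = arma::zeros(2);
          int nk = 0;
          for (int i = 0; i < I; ++i) {
            if ((int)dima(i) == k) {
              s(0) += d(i) - mu_item(0);
              s(1) += xi(i) - mu_item(1);
              ++nk;
            }
          }
          arma::vec pits = p_item * s;
          double lambda = N * p_person(k, k) + nk * p_item(0, 0);
          double lin = pits(0) - pp_all(k);
          double delta = lin / lambda + norm_rand() / std::sqrt(lambda);
          theta.col(k) += delta;
          for (int i = 0; i < I; ++i)
            if ((int)dima(i) == k) d(i) -= delta;
          pp_all += p_person.col(k) * (N * delta);
        }
      }
      if (!fix_tau && !fix_xi) {
        for (int k = 0; k < Ks; ++k) {
          arma::vec s = arma::zeros(2);
          int nk = 0;
          for (int i = 0; i < I; ++i) {
            if ((int)dims(i) == k) {
              s(0) += d(i) - mu_item(0);
              s(1) += xi(i) - mu_item(1);
              ++nk;
            }
          }
          arma::vec pits = p_item * s;
          int kk = Ka + k;
          double lambda = N * p_person(kk, kk) + nk * p_item(1, 1);
          double lin = -pits(1) - pp_all(kk);
          double delta = lin / lambda + norm_rand() / std::sqrt(lambda);
          tau.col(k) += delta;
          for (int i = 0; i < I; ++i)
            if ((int)dims(i) == k) xi(i) += delta;
          pp_all += p_person.col(kk) * (N * delta);
        }
      }
    }

    // -- residual variances sig2_i = omega_i^-2 | rest (conjugate IG)
    if (!fix_sig2) {
      for (int i = 0; i < I; ++i) {
        double ss = 0.0;
        int cnt = 0;
        for (int n = 0; n < N; ++n)
          if (maskT(n, i)) {
            double r = logT(n, i) - (xi(i) - tau(n, dims(i)));
            ss += r * r;
            ++cnt;
          }
        sig2(i) =
            1.0 / R::rgamma(ig_shape + 0.5 * cnt, 1.0 / (ig_rate + 0.5 * ss));
      }
    }

    // -- Sigma_person | persons (inverse-Wishart, person mean fixed at 0)
    if (!fix_sp) {
      arma::mat p_all(N, Kstar);
      if (Ka > 0) p_all.cols(0, Ka - 1) = theta;
      p_all.cols(Ka, Kstar - 1) = tau;
      arma::mat s = p_all.t() * p_all;
      sigma_person = rinvwishart(df_person + N, r_person + s);
    }

    // -- item hyperparameters
    arma::mat items(I, 2);
    items.col(0) = d;
    items.col(1) = xi;
    if (!fix_mu) {
      p_item = arma::inv_sympd(sigma_item);
      arma::mat p0(2, 2, arma::fill::zeros);
      p0(0, 0) = prec_mu_d;
      p0(1, 1) = prec_mu_xi;
      arma::vec m0 = {mu_d0, mu_xi0};
      arma::mat lambda = p0 + (double)I * p_item;
      arma::vec lin = p0 * m0 + p_item * arma::sum(items, 0).t();
      mu_item = mvn_from_precision(lambda, lin);
    }
    if (!fix_si) {
      arma::mat dev = items.each_row() - mu_item.t();
      sigma_item = rinvwishart(df_item + I, r_item + dev.t() * dev);
    }

    // -- bookkeeping
    bool at_report = verbose && report_every > 0 && (iter + 1) % report_every == 0;
    bool store =
        iter >= n_burnin && (iter - n_burnin) % thin == 0 && keep < n_keep;
    if (store || at_report) {
      double ll = state_loglik(Y, logT, maskY, maskT, dima, dims, theta, tau,
                               d, xi, sig2, use_y);
      if (!std::isfinite(ll))
        stop("non-finite log-likelihood at iteration %d; sampler diverged",
             iter + 1);
      if (at_report)
        Rprintf("iter %6d  loglik %.2f\n", iter + 1, ll);
      if (store) {
        if (use_y) theta_draws.slice(keep) = theta;
        tau_draws.slice(keep) = tau;
        d_draws.col(keep) = d;
        xi_draws.col(keep) = xi;
        omega_draws.col(keep) = 1.0 / arma::sqrt(sig2);
        sp_draws.slice(keep) = sigma_person;
        mu_item_draws.col(keep) = mu_item;
        si_draws.slice(keep) = sigma_item;
        loglik_draws(keep) = ll;
        ++keep;
      }
    }
  }

  return List::create(
      _["theta"] = theta_draws, _["tau"] = tau_draws, _["d"] = d_draws,
      _["xi"] = xi_draws, _["omega"] = omega_draws,
      _["sigma_person"] = sp_draws, _["mu_item"] = mu_item_draws,
      _["sigma_item"] = si_draws, _["loglik"] = loglik_draws,
      _["n_kept"] = keep);
}

// Exposed for unit testing of the augmentation primitive: n draws from
// PG(1, z). Moments of PG(1, z): mean tanh(z/2)/(2z).
// [[Rcpp::export(".rpolyagamma")]]
NumericVector rpolyagamma(int n, double z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z);
  return out;
}
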