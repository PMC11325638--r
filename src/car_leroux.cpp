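// MCMC sampler for the binomial Leroux CAR model:
//   y_i ~ Bernoulli(p_i),  logit(p_i) = x_i' beta + phi_i
//   phi  ~ N(0, tau2 * Q(rho)^{-1}),  Q(rho) = rho (D - W) + (1 - rho) I
// Updates: single-site random-walk Metropolis for each beta_j and each phi_i
// (step sizes adapted towards 40-50% acceptance during burn-in, frozen
// after), Gibbs for tau2 (inverse-gamma conjugacy), random-walk Metropolis
// for rho with the log-determinant evaluated from the precomputed
// eigenvalues of D - W. phi is recentred to mean zero every sweep with the
// mean absorbed into the intercept (the first column of X must be constant
// one). All randomness comes from R's RNG, so set.seed() in R makes a chain
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
List car_leroux_chain(const arma::vec& y,
                      const arma::mat& X,
                      const arma::ivec& adj,
                      const arma::ivec& adj_ptr,
                      const arma::vec& eigM,
                      int n_iter,
                      int burn_in,
                      arma::vec beta,
                      arma::vec phi,
                      double rho,
                      double tau2,
                      double beta_prior_var,
                      double tau2_shape,
                      double tau2_rate,
                      int phi_thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;

  arma::vec deg(n);
  for (int i = 0; i < n; ++i) deg[i] = adj_ptr[i + 1] - adj_ptr[i];

  arma::vec eta = X * beta + phi;

  // proposal step sizes, adapted during burn-in
  arma::vec sd_beta(p, arma::fill::value(0.1));
  double sd_phi = 0.5;
  double sd_rho = 0.05;
  double sd_scale = 0.1;
  arma::ivec acc_beta_win(p, arma::fill::zeros);
  int acc_phi_win = 0, acc_rho_win = 0, acc_scale_win = 0, win = 0;
  arma::ivec acc_beta_post(p, arma::fill::zeros);
  long long acc_phi_post = 0;
  int acc_rho_post = 0, n_post = 0;
  const int adapt_every = 50;

  arma::mat beta_store(n_iter, p);
  arma::vec rho_store(n_iter), tau2_store(n_iter);
  const int n_keep = (phi_thin > 0) ? n_iter / phi_thin : 0;
  arma::mat phi_store(std::max(n_keep, 0), n);
  arma::ivec phi_iters(std::max(n_keep, 0));

  for (int it = 0; it < n_iter; ++it) {
    const bool post = (it >= burn_in);
    ++win;
    if (post) ++n_post;

    // ---- beta: single-site random walk, full likelihood recomputed O(n)
    for (int j = 0; j < p; ++j) {
      const double delta = R::rnorm(0.0, sd_beta[j]);
      const double bnew = beta[j] + delta;
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        const double en = eta[i] + X(i, j) * delta;
        dll += y[i] * (en - eta[i]) - (log1pexp_(en) - log1pexp_(eta[i]));
      }
      dll += (beta[j] * beta[j] - bnew * bnew) / (2.0 * beta_prior_var);
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        for (int i = 0; i < n; ++i) eta[i] += X(i, j) * delta;
        beta[j] = bnew;
        ++acc_beta_win[j];
        if (post) ++acc_beta_post[j];
      }
    }

    // ---- phi: single-site random walk against Bernoulli likelihood and
    //      the Leroux full-conditional Gaussian prior
    for (int i = 0; i < n; ++i) {
      double nb_sum = 0.0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nb_sum += phi[adj[k]];
      const double denom = rho * deg[i] + 1.0 - rho;
      const double m = rho * nb_sum / denom;
      const double prec = denom / tau2;
      const double pnew = phi[i] + R::rnorm(0.0, sd_phi);
      const double en = eta[i] + (pnew - phi[i]);
      double dll = y[i] * (en - eta[i]) - (log1pexp_(en) - log1pexp_(eta[i]));
      dll -= 0.5 * prec * ((pnew - m) * (pnew - m) - (phi[i] - m) * (phi[i] - m));
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        eta[i] = en;
        phi[i] = pnew;
        ++acc_phi_win;
        if (post) ++acc_phi_post;
      }
    }

    // ---- identifiability: recentre phi, absorb the mean into the intercept
    const double pbar = arma::mean(phi);
    phi -= pbar;
    beta[0] += pbar; // X column 0 is the intercept, eta is unchanged

    // ---- quadratic forms phi' (D - W) phi and phi' phi
    double quad_lap = 0.0;
    for (int i = 0; i < n; ++i) {
      double nb_sum = 0.0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nb_sum += phi[adj[k]];
      quad_lap += phi[i] * (deg[i] * phi[i] - nb_sum);
    }
    const double quad_id = arma::dot(phi, phi);

    // ---- tau2: conjugate inverse-gamma Gibbs step
    const double quad = rho * quad_lap + (1.0 - rho) * quad_id;
    tau2 = 1.0 / R::rgamma(tau2_shape + 0.5 * n,
                           1.0 / (tau2_rate + 0.5 * quad));

    // ---- rho: random-walk Metropolis with eigenvalue log-determinant
    //      (several cheap updates per sweep; rho mixes slowly otherwise)
    for (int rep = 0; rep < 5; ++rep) {
      const double rnew = rho + R::rnorm(0.0, sd_rho);
      if (rnew >= 0.0 && rnew < 1.0) {
        double dld = 0.0;
        for (int k = 0; k < n; ++k) {
          dld += std::log(rnew * eigM[k] + 1.0 - rnew) -
                 std::log(rho * eigM[k] + 1.0 - rho);
        }
        const double dll = 0.5 * dld -
          (rnew - rho) * (quad_lap - quad_id) / (2.0 * tau2);
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          rho = rnew;
          ++acc_rho_win;
          if (post) ++acc_rho_post;
        }
      }
    }

    // ---- joint scale move: (phi, tau2) -> (c phi, c^2 tau2).
    //      The Leroux prior density of phi is invariant under this map, so
    //      the acceptance ratio needs only the likelihood, the tau2 prior,
    //      -n log c from the phi normalising constant, and the Jacobian
    //      (n + 2) log c. This lets the pair cross scales in one step where
    //      single-site moves would crawl (the usual variance-field funnel).
    {
      const double logc = R::rnorm(0.0, sd_scale);
      const double c = std::exp(logc);
      const double tau2_new = c * c * tau2;
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        const double en = eta[i] + (c - 1.0) * phi[i];
        dll += y[i] * (en - eta[i]) - (log1pexp_(en) - log1pexp_(eta[i]));
      }
      dll += -n * logc;                                   // phi prior constant
      dll += -(tau2_shape + 1.0) * (2.0 * logc)           // tau2 prior
             - tau2_rate * (1.0 / tau2_new - 1.0 / tau2);
      dll += (n + 2.0) * logc;                            // Jacobian
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        for (int i = 0; i < n; ++i) eta[i] += (c - 1.0) * phi[i];
        phi *= c;
        tau2 = tau2_new;
        ++acc_scale_win;
      }
    }


    // ---- adapt proposal step sizes during burn-in, freeze after
    if (!post && win == adapt_every) {
      for (int j = 0; j < p; ++j) {
        const double rate = acc_beta_win[j] / (double)adapt_every;
        sd_beta[j] *= std::exp(std::min(0.5, std::max(-0.5, rate - 0.45)));
        acc_beta_win[j] = 0;
      }
      const double rate_phi = acc_phi_win / (double)(adapt_every * n);
      sd_phi *= std::exp(std::min(0.5, std::max(-0.5, rate_phi - 0.45)));
      acc_phi_win = 0;
      const double rate_rho = acc_rho_win / (5.0 * adapt_every);
      sd_rho *= std::exp(std::min(0.5, std::max(-0.5, rate_rho - 0.45)));
      sd_rho = std::min(sd_rho, 0.5);
      acc_rho_win = 0;
      const double rate_scale = acc_scale_win / (double)adapt_every;
      sd_scale *= std::exp(std::min(0.5, std::max(-0.5, rate_scale - 0.45)));
      sd_scale = std::min(sd_scale, 1.0);
      acc_scale_win = 0;
      win = 0;
    }
    if (post) win = 0;

    beta_store.row(it) = beta.t();
    rho_store[it] = rho;
    tau2_store[it] = tau2;
    if (phi_thin > 0 && (it + 1) % phi_thin == 0) {
      const int r = (it + 1) / phi_thin - 1;
      if (r < n_keep) {
        phi_store.row(r) = phi.t();
        phi_iters[r] = it + 1;
      }
    }
  }

  const double np = std::max(n_post, 1);
  return List::create(
    _["beta"] = beta_store,
    _["rho"] = rho_store,
    _["tau2"] = tau2_store,
    _["phi"] = phi_store,
    _["phi_iters"] = phi_iters,
    _["accept"] = List::create(
      _["beta"] = arma::conv_to<arma::vec>::from(acc_beta_post) / np,
      _["phi"] = acc_phi_post / (np * n),
      _["rho"] = acc_rho_post / (5.0 * np)),
    _["step_sizes"] = List::create(
      _["beta"] = sd_beta, _["phi"] = sd_phi, _["rho"] = sd_rho,
      _["scale"] = sd_scale)
  );
}
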