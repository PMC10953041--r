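#include <Rcpp.h>
using namespace Rcpp;

// exp(Q t) v via uniformization. The caller supplies P = I + Q/lambda as a
// dgCMatrix (slots p, i, x) with lambda = max(-diag(Q)); P is substochastic
// row-wise non-negative. exp(Qt) v = sum_k dpois(k; lambda t) P^k v, truncated
// where the Poisson tail drops below tol.
// [[Rcpp::export]]
NumericVector unif_expmv(IntegerVector Pp, IntegerVector Pi, NumericVector Px,
                         int n, double lambda, NumericVector v, double t,
                         double tol = 1e-13) {
  NumericVector out(n);
  double lt = lambda * t;
  if (lt <= 0) {
    for (int k = 0; k < n; ++k) out[k] = v[k];
    return out;
  }
  int m = (int)R::qpois(1.0 - tol, lt, 1, 0) + 2;
  std::vector<double> w(v.begin(), v.end());
  std::vector<double> w2(n);
  double wk = R::dpois(0.0, lt, 0);
  for (int k = 0; k < n; ++k) out[k] = wk * w[k];
  for (int k = 1; k <= m; ++k) {
    // w2 = P^T? no: (P w): column-compressed, so accumulate column j into rows i
    std::fill(w2.begin(), w2.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double wj = w[j];
      if (wj == 0.0) continue;
      for (int idx = Pp[j]; idx < Pp[j + 1]; ++idx)
        w2[Pi[idx]] += Px[idx] * wj;
    }
    std::swap(w, w2);
    wk = R::dpois((double)k, lt, 0);
    if (wk > 0) {
      for (int i2 = 0; i2 < n; ++i2) out[i2] += wk * w[i2];
    }
  }
  return out;
}

static inline double branch_lpdf(double xc, double xp, double drift,
                                 double s2, double t) {
  double sd = std::sqrt(s2 * t);
  return R::dnorm(xc - xp, drift, sd, 1);
}

// Metropolis-Hastings sampler for Brownian motion with piecewise directional
// trend and latent node states.
//
// x0:        initial values for all nodes (length nnode_total); tips hold data
// is_latent: 1 where the state is sampled (internal nodes), 0 where fixed
// child/parent: 0-based node ids per branch; blen: branch lengths (Myr)
// Texp:      nbranch x nbins matrix, time spent by each branch in each bin
// root:      0-based id of the root node
// Priors (on the rescaled trait scale): sigma2 ~ half-Cauchy(scale 1),
// mu_k ~ Normal(0, sd 10), root state ~ Normal(0, sd 50).
// [[Rcpp::export]]
List bm_trend_mcmc(NumericVector x0, IntegerVector is_latent,
                   IntegerVector child, IntegerVector parent,
                   NumericVector blen, NumericMatrix Texp, int root,
                   double s2_init, NumericVector mu_init,
                   int n_gen, int burnin, int thin,
                   double win_x, double win_mu, double win_s2) {
  int nn = x0.size(), nb = child.size(), nbin = mu_init.size();
  std::vector<double> x(x0.begin(), x0.end());
  double s2 = s2_init;
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> drift(nb);
  auto set_drift = [&](void) {
    for (int b = 0; b < nb; ++b) {
      double d = 0.0;
      for (int k = 0; k < nbin; ++k) d += mu[k] * Texp(b, k);
      drift[b] = d;
    }
  };
  set_drift();

  // branches touching each node, for local updates
  std::vector<std::vector<int>> touch(nn);
  for (int b = 0; b < nb; ++b) {
    touch[child[b]].push_back(b);
    touch[parent[b]].push_back(b);
  }
  std::vector<int> latent;
  for (int i = 0; i < nn; ++i) if (is_latent[i]) latent.push_back(i);

  auto full_lp = [&](double s2v) {
    double lp = 0.0;
    for (int b = 0; b < nb; ++b)
      lp += branch_lpdf(x[child[b]], x[parent[b]], drift[b], s2v, blen[b]);
    return lp;
  };

  int n_keep = (n_gen - burnin) / thin;
  NumericVector s2_out(n_keep);
  NumericMatrix mu_out(n_keep, nbin);
  NumericMatrix x_out(n_keep, nn);
  double acc_x = 0, try_x = 0, acc_s2 = 0, try_s2 = 0, acc_mu = 0, try_mu = 0;
  int kept = 0;

  for (int g = 0; g < n_gen; ++g) {
    // latent node states: sliding-window updates, local likelihood ratio
    for (size_t li = 0; li < latent.size(); ++li) {
      int nd = latent[li];
      double prop = x[nd] + R::runif(-win_x, win_x);
      double lr = 0.0;
      for (size_t tb = 0; tb < touch[nd].size(); ++tb) {
        int b = touch[nd][tb];
        double xc = (child[b] == nd) ? prop : x[child[b]];
        double xp = (parent[b] == nd) ? prop : x[parent[b]];
        lr += branch_lpdf(xc, xp, drift[b], s2, blen[b]);
        lr -= branch_lpdf(x[child[b]], x[parent[b]], drift[b], s2, blen[b]);
      }
      if (nd == root)
        lr += R::dnorm(prop, 0.0, 50.0, 1) - R::dnorm(x[nd], 0.0, 50.0, 1);
      try_x += 1;
      if (std::log(R::runif(0, 1)) < lr) { x[nd] = prop; acc_x += 1; }
    }
    // sigma2: multiplicative proposal, half-Cauchy(1) prior, Jacobian s2'/s2
    {
      double prop = s2 * std::exp(R::runif(-win_s2, win_s2));
      double lr = full_lp(prop) - full_lp(s2);
      lr += std::log(1.0 + s2 * s2) - std::log(1.0 + prop * prop);
      lr += std::log(prop) - std::log(s2);
      try_s2 += 1;
      if (std::log(R::runif(0, 1)) < lr) { s2 = prop; acc_s2 += 1; }
    }
    // trend per bin: additive proposal, Normal(0, 10) prior
    for (int k = 0; k < nbin; ++k) {
      double old = mu[k];
      double prop = old + R::runif(-win_mu, win_mu);
      double lp_old = full_lp(s2);
      mu[k] = prop; set_drift();
      double lp_new = full_lp(s2);
      double lr = lp_new - lp_old +
        R::dnorm(prop, 0.0, 10.0, 1) - R::dnorm(old, 0.0, 10.0, 1);
      try_mu += 1;
      if (std::log(R::runif(0, 1)) < lr) {
        acc_mu += 1;
      } else {
        mu[k] = old; set_drift();
      }
    }
    // simple adaptation during burn-in only
    if (g < burnin && g > 0 && g % 200 == 0) {
      if (try_x > 0) {
        double r = acc_x / try_x;
        if (r < 0.2) win_x *= 0.8; else if (r > 0.45) win_x *= 1.25;
      }
      if (try_s2 > 0) {
        double r = acc_s2 / try_s2;
        if (r < 0.2) win_s2 *= 0.8; else if (r > 0.45) win_s2 *= 1.25;
      }
      if (try_mu > 0) {
        double r = acc_mu / try_mu;
        if (r < 0.2) win_mu *= 0.8; else if (r > 0.45) win_mu *= 1.25;
      }
      acc_x = try_x = acc_s2 = try_s2 = acc_mu = try_mu = 0;
    }
    if (g >= burnin && ((g - burnin) % thin == 0) && kept < n_keep) {
      s2_out[kept] = s2;
      for (int k = 0; k < nbin; ++k) mu_out(kept, k) = mu[k];
      for (int i = 0; i < nn; ++i) x_out(kept, i) = x[i];
      ++kept;
    }
  }

  return List::create(
    _["sigma2"] = s2_out, _["mu"] = mu_out, _["states"] = x_out,
    _["accept"] = NumericVector::create(
      _["x"] = try_x > 0 ? acc_x / try_x : NA_REAL,
      _["sigma2"] = try_s2 > 0 ? acc_s2 / try_s2 : NA_REAL,
      _["mu"] = try_mu > 0 ? acc_mu / try_mu : NA_REAL));
}
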