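// Metropolis-within-Gibbs sampler for a multivariate latent-normal
// (ordered probit) imputation model with provider random intercepts:
//
//   Z_i = B'x_i + u_{j(i)} + e_i,   e_i ~ N(0, Omega_e),
//   Omega_e compound symmetry with unit diagonal and correlation rho,
//   u_j^k = v_j + w_j^k with a common provider factor v_j ~ N(0, tau_c^2)
//   and item-specific effects w_j^k ~ N(0, tau_k^2) (level-2 compound
//   symmetry; a purely diagonal Omega_u cannot express a provider effect
//   shared across items),
//   observed category c  <=>  alpha_c < Z <= alpha_{c+1},
//
// with the first cut-point of every component fixed at 0 for
// identification (free per-component intercepts live in B). Cut-points
// move by a Cowles-type Metropolis step using the conditional category
// probabilities given the other components, followed by an immediate
// redraw of the component's latent values; rho moves by random-walk
// Metropolis on the compound-symmetry log-likelihood. Proposal scales
// adapt toward ~30% acceptance during burn-in only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rtrunc_norm(double mean, double sd, double lo, double hi) {
  double a = (lo - mean) / sd, b = (hi - mean) / sd;
  double pa = (a <= -8.0) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (b >=  8.0) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) {
    // interval far in a tail: pin to the nearest boundary
    double z = (a > 0.0) ? a : ((b < 0.0) ? b : 0.0);
    return mean + sd * std::min(std::max(z, -8.0), 8.0);
  }
  double u = pa + unif_rand() * (pb - pa);
  u = std::min(std::max(u, 1e-15), 1.0 - 1e-15);
  return mean + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
}

static inline double cat_lo(const std::vector<double>& thr, int c) {
  return (c == 0) ? -INFINITY : thr[c - 1];
}
static inline double cat_hi(const std::vector<double>& thr, int c, int ncat) {
  return (c == ncat - 1) ? INFINITY : thr[c];
}

static double interval_logprob(double lo, double hi, double mean, double sd) {
  double pb = (hi ==  INFINITY) ? 1.0 : R::pnorm((hi - mean) / sd, 0.0, 1.0, 1, 0);
  double pa = (lo == -INFINITY) ? 0.0 : R::pnorm((lo - mean) / sd, 0.0, 1.0, 1, 0);
  double p = pb - pa;
  return (p > 1e-300) ? std::log(p) : -691.0;  // log(1e-300)
}

// [[Rcpp::export]]
List ordinal_gibbs_cpp(IntegerMatrix H, arma::mat X, IntegerVector prov,
                       int J, IntegerVector ncat, List thr_init,
                       double rho_init, int burn, int n_keep, int thin,
                       double prior_a = 0.001, double prior_b = 0.001,
                       bool adapt = true, bool sample_rho = true) {
  const int n = H.nrow(), K = H.ncol(), p = X.n_cols;
  if (K < 2) stop("need at least two latent components");

  std::vector<std::vector<double> > thr(K);
  for (int k = 0; k < K; ++k) {
    NumericVector tk = thr_init[k];
    thr[k] = std::vector<double>(tk.begin(), tk.end());
    if ((int)thr[k].size() != ncat[k] - 1) stop("thr_init length mismatch");
  }

  arma::mat XtX = X.t() * X;
  arma::mat XtX_inv;
  if (!arma::inv_sympd(XtX_inv, XtX)) stop("singular predictor matrix");
  arma::mat Lx = arma::chol(XtX_inv, "lower");

  // provider bookkeeping
  std::vector<int> nj(J, 0);
  for (int i = 0; i < n; ++i) nj[prov[i]]++;

  double rho = rho_init;
  const double rho_lb = std::max(-1.0 / (K - 1) + 0.02, -0.95);
  arma::mat B(p, K, arma::fill::zeros);
  arma::mat W(J, K, arma::fill::zeros);   // item-specific provider effects
  arma::vec vprov(J, arma::fill::zeros);  // common provider factor
  arma::mat U(J, K, arma::fill::zeros);   // u = v + w, used downstream
  arma::vec tau2(K, arma::fill::ones);
  tau2 *= 0.05;
  double tauc2 = 0.05;

  // latent init: interval midpoints for observed, 0 for missing
  arma::mat Z(n, K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      int c = H(i, k);
      if (c == NA_INTEGER) { Z(i, k) = 0.0; continue; }
      double lo = cat_lo(thr[k], c), hi = cat_hi(thr[k], c, ncat[k]);
      double l = (lo == -INFINITY) ? hi - 1.0 : lo;
      double h = (hi ==  INFINITY) ? lo + 1.0 : hi;
      Z(i, k) = 0.5 * (l + h);
    }
  }

  // start B, u and tau at empirical values: the centred hierarchical
  // parameterisation mixes slowly out of the tau ~ 0 region, so a
  // cold (u = 0) start can trap the provider effects near zero
  B = XtX_inv * (X.t() * Z);
  {
    arma::mat resid = Z - X * B;
    arma::mat usum(J, K, arma::fill::zeros);
    for (int i = 0; i < n; ++i) usum.row(prov[i]) += resid.row(i);
    for (int j = 0; j < J; ++j) {
      if (nj[j] > 0) U.row(j) = usum.row(j) / (double)nj[j];
      vprov(j) = arma::mean(U.row(j));
      W.row(j) = U.row(j) - vprov(j);
    }
    double mv = arma::mean(vprov);
    tauc2 = std::max(arma::mean(arma::square(vprov - mv)), 0.01);
    for (int k = 0; k < K; ++k) {
      double m = arma::mean(W.col(k));
      double v = arma::mean(arma::square(W.col(k) - m));
      tau2(k) = std::max(v, 0.005);
    }
  }

  // proposal scales and acceptance counters
  std::vector<double> s_thr(K, 0.05);
  double s_rho = 0.02, s_scale = 0.3;
  std::vector<int> acc_thr(K, 0), try_thr(K, 0);
  int acc_rho = 0, try_rho = 0, acc_scale = 0, try_scale = 0;
  std::vector<double> final_acc_thr(K, NA_REAL);
  double final_acc_rho = NA_REAL;

  List imps(n_keep), states(n_keep);
  int kept = 0;
  const int n_iter = burn + n_keep * thin;

  // residual workspace
  arma::mat Mu(n, K), E(n, K);
  arma::vec s1(n);

  for (int t = 1; t <= n_iter; ++t) {
    // conditional moments under compound symmetry
    double c1 = rho / (1.0 + (K - 2) * rho);
    double v  = (1.0 - rho) * (1.0 + (K - 1) * rho) / (1.0 + (K - 2) * rho);
    double sv = std::sqrt(v);

    Mu = X * B;
    for (int i = 0; i < n; ++i) Mu.row(i) += U.row(prov[i]);
    E = Z - Mu;
    s1 = arma::sum(E, 1);

    // (1) latent values, component by component
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double m = Mu(i, k) + c1 * (s1(i) - E(i, k));
        double znew;
        int c = H(i, k);
        if (c == NA_INTEGER) {
          znew = m + sv * norm_rand();
        } else {
          znew = rtrunc_norm(m, sv, cat_lo(thr[k], c), cat_hi(thr[k], c, ncat[k]));
        }
        s1(i) += znew - Z(i, k);
        E(i, k) = znew - Mu(i, k);
        Z(i, k) = znew;
      }
    }

    // (2) cut-points: Cowles-type Metropolis with immediate latent redraw
    for (int k = 0; k < K; ++k) {
      if (ncat[k] < 3) continue;  // binary: single cut-point fixed at 0
      try_thr[k]++;
      std::vector<double> prop = thr[k];
      bool ok = true;
      for (int m = 1; m < ncat[k] - 1; ++m) {  // thr[0] fixed at 0
        prop[m] = thr[k][m] + s_thr[k] * norm_rand();
      }
      for (int m = 1; m < ncat[k] - 1; ++m) {
        if (prop[m] <= prop[m - 1]) { ok = false; break; }
      }
      if (ok) {
        double lr = 0.0;
        for (int i = 0; i < n; ++i) {
          int c = H(i, k);
          if (c == NA_INTEGER) continue;
          double m = Mu(i, k) + c1 * (s1(i) - E(i, k));
          lr += interval_logprob(cat_lo(prop, c), cat_hi(prop, c, ncat[k]), m, sv)
              - interval_logprob(cat_lo(thr[k], c), cat_hi(thr[k], c, ncat[k]), m, sv);
        }
        if (std::log(unif_rand()) < lr) {
          acc_thr[k]++;
          thr[k] = prop;
          for (int i = 0; i < n; ++i) {
            int c = H(i, k);
            if (c == NA_INTEGER) continue;
            double m = Mu(i, k) + c1 * (s1(i) - E(i, k));
            double znew = rtrunc_norm(m, sv, cat_lo(thr[k], c),
                                      cat_hi(thr[k], c, ncat[k]));
            s1(i) += znew - Z(i, k);
            E(i, k) = znew - Mu(i, k);
            Z(i, k) = znew;
          }
        }
      }
    }

    // (3) latent-regression coefficients, matrix-normal draw
    arma::mat Zstar = Z;
    for (int i = 0; i < n; ++i) Zstar.row(i) -= U.row(prov[i]);
    arma::mat Omega(K, K);
    Omega.fill(rho); Omega.diag().ones();
    arma::mat Le = arma::chol(Omega, "lower");
    arma::mat G(p, K);
    for (int a = 0; a < p; ++a) for (int k = 0; k < K; ++k) G(a, k) = norm_rand();
    arma::mat Bhat = XtX_inv * (X.t() * Zstar);
    B = Bhat + Lx * G * Le.t();

    // (4) provider random effects
    arma::mat Oinv(K, K);
    {
      double d = 1.0 / (1.0 - rho);
      double off = rho / ((1.0 - rho) * (1.0 + (K - 1) * rho));
      Oinv.fill(-off); Oinv.diag().fill(d - off);
      // CS inverse: (I - rho/(1+(K-1)rho) * ones)/ (1-rho)
    }
    arma::mat Rsum(J, K, arma::fill::zeros);
    arma::mat XB = X * B;
    for (int i = 0; i < n; ++i) Rsum.row(prov[i]) += Z.row(i) - XB.row(i);
    const double ones_oinv = (double)K / (1.0 + (K - 1) * rho); // 1' Oinv 1
    for (int j = 0; j < J; ++j) {
      // item-specific effects w_j | v_j
      arma::vec Sadj = Rsum.row(j).t() - nj[j] * vprov(j) * arma::ones(K);
      arma::mat Prec = nj[j] * Oinv;
      for (int k = 0; k < K; ++k) Prec(k, k) += 1.0 / tau2(k);
      arma::mat Ruc = arma::chol(Prec);  // upper
      arma::vec mean = arma::solve(Prec, Oinv * Sadj,
                                   arma::solve_opts::likely_sympd);
      arma::vec g(K);
      for (int k = 0; k < K; ++k) g(k) = norm_rand();
      W.row(j) = (mean + arma::solve(arma::trimatu(Ruc), g)).t();
      // common factor v_j | w_j: 1' Oinv x = sum(x) / (1 + (K-1) rho)
      double num = (arma::accu(Rsum.row(j)) - nj[j] * arma::accu(W.row(j))) /
                   (1.0 + (K - 1) * rho);
      double prec_v = 1.0 / tauc2 + nj[j] * ones_oinv;
      vprov(j) = num / prec_v + norm_rand() / std::sqrt(prec_v);
      U.row(j) = W.row(j) + vprov(j);
    }

    // (5) level-2 variances
    for (int k = 0; k < K; ++k) {
      double ss = arma::dot(W.col(k), W.col(k));
      double shape = prior_a + 0.5 * J;
      double rate = prior_b + 0.5 * ss;
      tau2(k) = std::max(1.0 / R::rgamma(shape, 1.0 / rate), 1e-10);
    }
    {
      double ss = arma::dot(vprov, vprov);
      tauc2 = std::max(1.0 / R::rgamma(prior_a + 0.5 * J,
                                       1.0 / (prior_b + 0.5 * ss)), 1e-10);
    }

    // (5b) joint rescaling move on (u, tau): the centred parameterisation
    // is metastable near tau = 0 (data-augmented latent draws attenuate the
    // provider signal whenever u is small), so a generalised-Gibbs scaling
    // transformation u -> s u, tau^2 -> s^2 tau^2 is proposed each
    // iteration; acceptance is the posterior ratio times the Jacobian
    // s^(JK + 2K) (the normal-prior ratio contributes s^(-JK)).
    {
      try_scale++;
      double sumA = 0.0, sumB = 0.0;
      for (int j = 0; j < J; ++j) {
        arma::vec uj = U.row(j).t();
        arma::vec Ou = Oinv * uj;
        sumA += nj[j] * arma::dot(uj, Ou);
        sumB += arma::dot(Ou, Rsum.row(j).t());
      }
      double eps = s_scale * norm_rand();
      double s = std::exp(eps);
      double dlik = -0.5 * ((s * s - 1.0) * sumA - 2.0 * (s - 1.0) * sumB);
      double dprior = -2.0 * (K + 1) * prior_a * eps
        - prior_b * (1.0 / (s * s) - 1.0) *
          (arma::accu(1.0 / tau2) + 1.0 / tauc2);
      if (std::log(unif_rand()) < dlik + dprior) {
        U *= s;
        W *= s;
        vprov *= s;
        tau2 *= s * s;
        tauc2 *= s * s;
        acc_scale++;
      }
    }

    // (6) residual correlation, random-walk Metropolis
    if (sample_rho) {
      try_rho++;
      Mu = XB;
      for (int i = 0; i < n; ++i) Mu.row(i) += U.row(prov[i]);
      E = Z - Mu;
      s1 = arma::sum(E, 1);
      double ss2 = arma::accu(E % E);
      double ss1 = arma::dot(s1, s1);
      double prop = rho + s_rho * norm_rand();
      if (prop > rho_lb && prop < 0.995) {
        auto ll = [&](double r) {
          double a = 1.0 + (K - 1) * r;
          return -0.5 * n * ((K - 1) * std::log(1.0 - r) + std::log(a))
                 - 0.5 / (1.0 - r) * (ss2 - r / a * ss1);
        };
        if (std::log(unif_rand()) < ll(prop) - ll(rho)) { rho = prop; acc_rho++; }
      }
    }

    // adapt proposal scales during burn-in only
    if (adapt && t <= burn && t % 50 == 0) {
      for (int k = 0; k < K; ++k) {
        if (try_thr[k] > 0) {
          double rate = (double)acc_thr[k] / try_thr[k];
          s_thr[k] = std::min(std::max(s_thr[k] * std::exp(rate - 0.3), 0.002), 2.0);
        }
        acc_thr[k] = 0; try_thr[k] = 0;
      }
      if (try_rho > 0) {
        double rate = (double)acc_rho / try_rho;
        s_rho = std::min(std::max(s_rho * std::exp(rate - 0.3), 0.002), 1.0);
      }
      acc_rho = 0; try_rho = 0;
      if (try_scale > 0) {
        double rate = (double)acc_scale / try_scale;
        s_scale = std::min(std::max(s_scale * std::exp(rate - 0.3), 0.01), 1.0);
      }
      acc_scale = 0; try_scale = 0;
    }
    if (t == burn) {  // reset counters so reported rates cover sampling phase
      for (int k = 0; k < K; ++k) { acc_thr[k] = 0; try_thr[k] = 0; }
      acc_rho = 0; try_rho = 0; acc_scale = 0; try_scale = 0;
    }

    // emit a completed dataset
    if (t > burn && (t - burn) % thin == 0) {
      IntegerMatrix Hc = clone(H);
      for (int k = 0; k < K; ++k) {
        for (int i = 0; i < n; ++i) {
          if (H(i, k) == NA_INTEGER) {
            int c = 0;
            for (size_t m = 0; m < thr[k].size(); ++m) if (Z(i, k) > thr[k][m]) c++;
            Hc(i, k) = c;
          }
        }
      }
      List thr_out(K);
      for (int k = 0; k < K; ++k) thr_out[k] = NumericVector(thr[k].begin(), thr[k].end());
      states[kept] = List::create(_["B"] = B, _["u"] = U,
                                  _["tau2"] = NumericVector(tau2.begin(), tau2.end()),
                                  _["tauc2"] = tauc2,
                                  _["rho"] = rho, _["thresholds"] = thr_out);
      imps[kept] = Hc;
      kept++;
    }
  }

  for (int k = 0; k < K; ++k) {
    final_acc_thr[k] = (try_thr[k] > 0) ? (double)acc_thr[k] / try_thr[k] : NA_REAL;
  }
  final_acc_rho = (try_rho > 0) ? (double)acc_rho / try_rho : NA_REAL;

  double final_acc_scale = (try_scale > 0) ? (double)acc_scale / try_scale : NA_REAL;
  return List::create(_["imputations"] = imps, _["states"] = states,
                      _["acc_thresholds"] = NumericVector(final_acc_thr.begin(), final_acc_thr.end()),
                      _["acc_rho"] = final_acc_rho,
                      _["acc_scale"] = final_acc_scale,
                      _["scales"] = List::create(_["thr"] = NumericVector(s_thr.begin(), s_thr.end()),
                                                 _["rho"] = s_rho));
}
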