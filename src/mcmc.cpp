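#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)) without overflow; accurate across the whole real line
static inline double stable_log1pexp(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

// Bernoulli(logit) log pmf contribution for one observation
static inline double bern_ll(int y, double eta) {
  return (double)y * eta - stable_log1pexp(eta);
}

// Adaptive Metropolis-within-Gibbs sampler for the BYM spatio-temporal
// multilevel logistic model:
//   y_i ~ Bernoulli(inv_logit(eta_i)),
//   eta_i = x_i' coef + u_{area(i)} + v_{area(i)},
// where X carries the intercept, covariate dummies and the centred t, t^2
// columns; u has an intrinsic CAR prior (sum-to-zero, precision tau_u) and
// v is iid Normal(0, 1/tau_v).  Random-walk Metropolis on each scalar
// coefficient and each u_j, v_j; conjugate Gibbs for tau_u, tau_v.
//
// All randomness comes from R's RNG: a set.seed() before the call makes the
// whole run reproducible, and the per-iteration draw sequence is fixed so
// extending n_iter leaves the common prefix of the chain identical.
// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector y,
                  NumericMatrix X,
                  IntegerVector area,          // 0-based area index per patient
                  List nb,                     // per-area 0-based neighbour indices
                  List nbw,                    // per-area neighbour weights
                  int n_comp,                  // connected components of the graph
                  NumericVector coef_prec,     // prior precision per column of X
                  double a_u, double b_u, double a_v, double b_v,
                  int n_iter, int burn_in, int thin,
                  NumericVector init_coef, double init_tau_u, double init_tau_v,
                  NumericVector init_u, NumericVector init_v,
                  double lik_weight,
                  bool spatial,
                  bool store_loglik,
                  bool update_u, bool update_v,
                  double target_acc) {
  const int n = y.size();
  const int p = X.ncol();
  const int J = nb.size();

  // sparse column representation of X (dummy columns are mostly zero)
  std::vector< std::vector<int> > cidx(p);
  std::vector< std::vector<double> > cval(p);
  for (int k = 0; k < p; ++k) {
    for (int i = 0; i < n; ++i) {
      double xv = X(i, k);
      if (xv != 0.0) { cidx[k].push_back(i); cval[k].push_back(xv); }
    }
  }

  // patients grouped by area
  std::vector< std::vector<int> > aidx(J);
  for (int i = 0; i < n; ++i) aidx[area[i]].push_back(i);

  // neighbour structure
  std::vector< std::vector<int> > nbi(J);
  std::vector< std::vector<double> > nbww(J);
  std::vector<double> dvec(J, 0.0);   // weighted degree
  for (int j = 0; j < J; ++j) {
    IntegerVector v1 = nb[j];
    NumericVector w1 = nbw[j];
    nbi[j].assign(v1.begin(), v1.end());
    nbww[j].assign(w1.begin(), w1.end());
    for (int m = 0; m < (int)nbww[j].size(); ++m) dvec[j] += nbww[j][m];
  }

  // state
  std::vector<double> coef(init_coef.begin(), init_coef.end());
  std::vector<double> u(init_u.begin(), init_u.end());
  std::vector<double> v(init_v.begin(), init_v.end());
  double tau_u = init_tau_u, tau_v = init_tau_v;

  std::vector<double> eta(n, 0.0);
  for (int k = 0; k < p; ++k)
    for (size_t m = 0; m < cidx[k].size(); ++m)
      eta[cidx[k][m]] += cval[k][m] * coef[k];
  if (spatial)
    for (int i = 0; i < n; ++i) eta[i] += u[area[i]] + v[area[i]];

  for (int i = 0; i < n; ++i)
    if (!R_finite(eta[i]))
      stop("non-finite linear predictor at initialization; use weaker starting values");

  // cached pointwise log likelihood at the current state
  std::vector<double> llcur(n);
  for (int i = 0; i < n; ++i) llcur[i] = bern_ll(y[i], eta[i]);
  std::vector<double> llprop;
  llprop.reserve(n);

  // adaptive random-walk step sizes (log scale)
  std::vector<double> ls_coef(p, std::log(0.1));
  std::vector<double> ls_u(J, std::log(0.5)), ls_v(J, std::log(0.5));
  std::vector<long> acc_coef(p, 0), prop_coef(p, 0);
  long acc_u = 0, prop_u = 0, acc_v = 0, prop_v = 0;

  const int n_ret = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  NumericMatrix coef_draws(n_ret, p);
  NumericMatrix u_draws(spatial ? n_ret : 0, spatial ? J : 0);
  NumericMatrix v_draws(spatial ? n_ret : 0, spatial ? J : 0);
  NumericMatrix tau_draws(n_ret, 2);
  NumericMatrix ll_draws(store_loglik ? n_ret : 0, store_loglik ? n : 0);
  // streaming WAIC accumulators over retained draws
  std::vector<double> acc_p(n, 0.0), acc_ll(n, 0.0), acc_ll2(n, 0.0);

  int s = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = (iter <= burn_in);
    const double gamma = adapting ? (1.0 / std::sqrt((double)iter)) : 0.0;

    // --- scalar coefficients: adaptive random walk ---
    for (int k = 0; k < p; ++k) {
      double step = std::exp(ls_coef[k]);
      double prop = coef[k] + step * R::norm_rand();
      double d = prop - coef[k];
      double dlp = -0.5 * coef_prec[k] * (prop * prop - coef[k] * coef[k]);
      const std::vector<int>& ci = cidx[k];
      const std::vector<double>& cv = cval[k];
      if (lik_weight != 0.0) {
        double dll = 0.0;
        llprop.resize(ci.size());
        for (size_t m = 0; m < ci.size(); ++m) {
          int i = ci[m];
          llprop[m] = bern_ll(y[i], eta[i] + cv[m] * d);
          dll += llprop[m] - llcur[i];
        }
        dlp += lik_weight * dll;
      }
      double uu = R::unif_rand();
      bool acc = R_finite(dlp) && (std::log(uu) < dlp);
      if (acc) {
        for (size_t m = 0; m < ci.size(); ++m) {
          int i = ci[m];
          eta[i] += cv[m] * d;
          if (lik_weight != 0.0) llcur[i] = llprop[m];
          else llcur[i] = bern_ll(y[i], eta[i]);
        }
        coef[k] = prop;
        if (!adapting) ++acc_coef[k];
      }
      if (!adapting) ++prop_coef[k];
      if (adapting) ls_coef[k] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
    }

    if (spatial) {
      // --- structured effects u_j: single-site RW against likelihood + CAR
      //     full conditional u_j | u_-j ~ N(weighted neighbour mean, 1/(tau_u d_j))
      if (update_u) {
        for (int j = 0; j < J; ++j) {
          double step = std::exp(ls_u[j]);
          double z = R::norm_rand();
          double uu = R::unif_rand();
          if (dvec[j] <= 0.0) continue;  // isolated area: u_j pinned at 0
          double prop = u[j] + step * z;
          double nbm = 0.0;
          for (size_t m = 0; m < nbi[j].size(); ++m) nbm += nbww[j][m] * u[nbi[j][m]];
          nbm /= dvec[j];
          double dlp = -0.5 * tau_u * dvec[j] *
            ((prop - nbm) * (prop - nbm) - (u[j] - nbm) * (u[j] - nbm));
          const std::vector<int>& ai = aidx[j];
          if (lik_weight != 0.0) {
            double dll = 0.0;
            llprop.resize(ai.size());
            for (size_t m = 0; m < ai.size(); ++m) {
              int i = ai[m];
              llprop[m] = bern_ll(y[i], eta[i] + (prop - u[j]));
              dll += llprop[m] - llcur[i];
            }
            dlp += lik_weight * dll;
          }
          bool acc = R_finite(dlp) && (std::log(uu) < dlp);
          if (acc) {
            double d = prop - u[j];
            for (size_t m = 0; m < ai.size(); ++m) {
              int i = ai[m];
              eta[i] += d;
              if (lik_weight != 0.0) llcur[i] = llprop[m];
              else llcur[i] = bern_ll(y[i], eta[i]);
            }
            u[j] = prop;
            if (!adapting) ++acc_u;
          }
          if (!adapting) ++prop_u;
          if (adapting) ls_u[j] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
        }
        // recentre u to sum zero, absorbing the mean into the intercept;
        // eta is unchanged so no recomputation is needed
        double um = 0.0;
        for (int j = 0; j < J; ++j) um += u[j];
        um /= (double)J;
        for (int j = 0; j < J; ++j) u[j] -= um;
        coef[0] += um;
      }

      // --- heterogeneity effects v_j ---
      if (update_v) {
        for (int j = 0; j < J; ++j) {
          double step = std::exp(ls_v[j]);
          double prop = v[j] + step * R::norm_rand();
          double dlp = -0.5 * tau_v * (prop * prop - v[j] * v[j]);
          const std::vector<int>& ai = aidx[j];
          if (lik_weight != 0.0) {
            double dll = 0.0;
            llprop.resize(ai.size());
            for (size_t m = 0; m < ai.size(); ++m) {
              int i = ai[m];
              llprop[m] = bern_ll(y[i], eta[i] + (prop - v[j]));
              dll += llprop[m] - llcur[i];
            }
            dlp += lik_weight * dll;
          }
          double uu = R::unif_rand();
          bool acc = R_finite(dlp) && (std::log(uu) < dlp);
          if (acc) {
            double d = prop - v[j];
            for (size_t m = 0; m < ai.size(); ++m) {
              int i = ai[m];
              eta[i] += d;
              if (lik_weight != 0.0) llcur[i] = llprop[m];
              else llcur[i] = bern_ll(y[i], eta[i]);
            }
            v[j] = prop;
            if (!adapting) ++acc_v;
          }
          if (!adapting) ++prop_v;
          if (adapting) ls_v[j] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
        }
      }

      // --- conjugate Gibbs draws for the precisions ---
      // pairwise CAR sum: sum_{j<k} w_jk (u_j - u_k)^2
      double ssu = 0.0;
      for (int j = 0; j < J; ++j)
        for (size_t m = 0; m < nbi[j].size(); ++m) {
          double dd = u[j] - u[nbi[j][m]];
          ssu += nbww[j][m] * dd * dd;
        }
      ssu *= 0.5;  // each unordered pair was counted twice
      double ssv = 0.0;
      for (int j = 0; j < J; ++j) ssv += v[j] * v[j];
      tau_u = R::rgamma(a_u + 0.5 * (double)(J - n_comp), 1.0 / (b_u + 0.5 * ssu));
      tau_v = R::rgamma(a_v + 0.5 * (double)J, 1.0 / (b_v + 0.5 * ssv));
    }

    // --- retain ---
    if (iter > burn_in && ((iter - burn_in) % thin == 0)) {
      for (int k = 0; k < p; ++k) coef_draws(s, k) = coef[k];
      if (spatial) {
        for (int j = 0; j < J; ++j) { u_draws(s, j) = u[j]; v_draws(s, j) = v[j]; }
      }
      tau_draws(s, 0) = tau_u;
      tau_draws(s, 1) = tau_v;
      for (int i = 0; i < n; ++i) {
        double ll = llcur[i];
        acc_p[i] += std::exp(ll);
        acc_ll[i] += ll;
        acc_ll2[i] += ll * ll;
        if (store_loglik) ll_draws(s, i) = ll;
      }
      ++s;
    }
  }

  NumericVector coef_acc(p);
  for (int k = 0; k < p; ++k)
    coef_acc[k] = prop_coef[k] > 0 ? (double)acc_coef[k] / prop_coef[k] : NA_REAL;

  return List::create(
    _["coef"] = coef_draws,
    _["u"] = u_draws,
    _["v"] = v_draws,
    _["tau"] = tau_draws,
    _["loglik"] = store_loglik ? (SEXP)ll_draws : R_NilValue,
    _["waic_acc"] = List::create(
      _["n_draws"] = n_ret,
      _["sum_p"] = NumericVector(acc_p.begin(), acc_p.end()),
      _["sum_ll"] = NumericVector(acc_ll.begin(), acc_ll.end()),
      _["sum_ll2"] = NumericVector(acc_ll2.begin(), acc_ll2.end())),
    _["acceptance"] = List::create(
      _["coef"] = coef_acc,
      _["u"] = prop_u > 0 ? (double)acc_u / prop_u : NA_REAL,
      _["v"] = prop_v > 0 ? (double)acc_v / prop_v : NA_REAL));
}
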