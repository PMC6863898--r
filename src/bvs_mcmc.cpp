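// Spike-and-slab Bayesian variable-selection sampler for one SNP region.
//
// Model: response r = mu * 1 + X_g beta + e, e ~ N(0, I) (unit residual
// variance; in probit mode r is the latent liability z whose sign is tied
// to the observed 0/1 phenotype).  beta_j ~ N(0, sigma_a^2) with
// sigma_a^2 = h / ((1 - h) * sum_{j in g} s_j^2), tying h to the proportion
// of phenotypic variance explained by the included SNPs; mu ~ N(0, v0).
// (mu, beta) are integrated out analytically for model moves, so the chain
// runs on (gamma, h, log10 pi[, z]).
//
// The inner linear algebra is written on small reused buffers (model size
// is capped at a handful of SNPs) because the sampler is rerun tens of
// thousands of times by the permutation engine.
//
// All randomness goes through R's RNG (RNGScope) so runs are reproducible
// from R-side seeds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr double NEG_INF = -std::numeric_limits<double>::infinity();

// Dense symmetric solver workspace for models up to `dim` coefficients
// (intercept + capped number of SNPs).
struct SmallChol {
  int dim;
  std::vector<double> A, L, b, u, w;
  explicit SmallChol(int d) : dim(d), A(d * d), L(d * d), b(d), u(d), w(d) {}

  // in-place lower Cholesky of A (m x m); returns false if not SPD
  bool factor(int m) {
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = A[i * dim + j];
        for (int k = 0; k < j; ++k) s -= L[i * dim + k] * L[j * dim + k];
        if (i == j) {
          if (s <= 0.0) return false;
          L[i * dim + i] = std::sqrt(s);
        } else {
          L[i * dim + j] = s / L[j * dim + j];
        }
      }
    }
    return true;
  }
  double logdet(int m) const {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += std::log(L[i * dim + i]);
    return 2.0 * s;
  }
  // forward solve L u = b
  void fsolve(int m) {
    for (int i = 0; i < m; ++i) {
      double s = b[i];
      for (int k = 0; k < i; ++k) s -= L[i * dim + k] * u[k];
      u[i] = s / L[i * dim + i];
    }
  }
  // back solve L' w = rhs (rhs in w)
  void bsolve(int m) {
    for (int i = m - 1; i >= 0; --i) {
      double s = w[i];
      for (int k = i + 1; k < m; ++k) s -= L[k * dim + i] * w[k];
      w[i] = s / L[i * dim + i];
    }
  }
};

// N(m, 1) truncated to (0, Inf) if `positive`, else to (-Inf, 0].
double rtruncnorm01(double m, bool positive) {
  if (positive) {
    if (m > -1.0) {                                  // acceptance >= 0.16
      for (int it = 0; it < 64; ++it) {
        double z = m + norm_rand();
        if (z > 0.0) return z;
      }
    }
    double T = R::pnorm(m, 0.0, 1.0, 1, 0);          // P(e > -m)
    double v = std::max(unif_rand() * T, 1e-300);
    return m + R::qnorm(v, 0.0, 1.0, 0, 0);          // upper-tail quantile
  } else {
    if (m < 1.0) {
      for (int it = 0; it < 64; ++it) {
        double z = m + norm_rand();
        if (z <= 0.0) return z;
      }
    }
    double T = R::pnorm(-m, 0.0, 1.0, 1, 0);         // P(e <= -m)
    double v = std::max(unif_rand() * T, 1e-300);
    return m + R::qnorm(v, 0.0, 1.0, 1, 0);
  }
}

double reflect_into(double x, double lo, double hi) {
  if (lo >= hi) return lo;
  while (x < lo || x > hi) {
    if (x < lo) x = lo + (lo - x);
    else x = hi - (x - hi);
  }
  return x;
}

struct Engine {
  const arma::mat& X;
  const arma::vec& snp_var;
  arma::mat gram;                 // (p+1) x (p+1) cross-products of [1, X]
  int n, p;
  double v0;                      // intercept prior variance
  SmallChol ws;

  Engine(const arma::mat& X_, const arma::vec& sv, double v0_, int max_k)
    : X(X_), snp_var(sv), n((int)X_.n_rows), p((int)X_.n_cols),
      v0(v0_), ws(max_k + 2) {
    arma::mat W(n, p + 1);
    W.col(0).ones();
    W.cols(1, p) = X;
    gram = W.t() * W;
  }

  double dot_col(int j, const double* r) const {
    const double* x = X.colptr(j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * r[i];
    return s;
  }

  // Fill ws.A and ws.b for inclusion set incl at variance-explained h;
  // returns log of the prior determinant term, or NaN on invalid h.
  double fill_system(const std::vector<int>& incl, double h,
                     double wtr0, const double* wtr) {
    const int k = (int)incl.size();
    double log_prior_det = std::log(v0);
    double inv_sa2 = 0.0;
    if (k > 0) {
      double sv = 0.0;
      for (int j : incl) sv += snp_var[j];
      double sa2 = h / ((1.0 - h) * sv);
      inv_sa2 = 1.0 / sa2;
      log_prior_det += k * std::log(sa2);
    }
    const int d = ws.dim;
    ws.A[0] = gram(0, 0) + 1.0 / v0;
    ws.b[0] = wtr0;
    for (int a = 0; a < k; ++a) {
      double g0 = gram(0, incl[a] + 1);
      ws.A[(a + 1) * d] = ws.A[a + 1] = g0;
      ws.b[a + 1] = wtr[a];
      for (int c = 0; c <= a; ++c) {
        double g = gram(incl[a] + 1, incl[c] + 1);
        ws.A[(a + 1) * d + (c + 1)] = ws.A[(c + 1) * d + (a + 1)] = g;
      }
      ws.A[(a + 1) * d + (a + 1)] += inv_sa2;
    }
    return log_prior_det;
  }

  // log marginal likelihood with (mu, beta) integrated out
  double logml(const std::vector<int>& incl, double h,
               double wtr0, const double* wtr, double rr) {
    const int m = (int)incl.size() + 1;
    double lpd = fill_system(incl, h, wtr0, wtr);
    if (!ws.factor(m)) return NEG_INF;
    ws.fsolve(m);
    double quad = 0.0;
    for (int i = 0; i < m; ++i) quad += ws.u[i] * ws.u[i];
    return -0.5 * n * std::log(2.0 * M_PI)
           - 0.5 * (ws.logdet(m) + lpd)
           - 0.5 * (rr - quad);
  }

  // Gibbs draw of (mu, beta) from the conjugate normal posterior
  void draw_coefs(const std::vector<int>& incl, double h,
                  double wtr0, const double* wtr,
                  double& mu, std::vector<double>& beta) {
    const int k = (int)incl.size();
    const int m = k + 1;
    fill_system(incl, h, wtr0, wtr);
    ws.factor(m);
    ws.fsolve(m);                          // u = L^-1 b
    for (int i = 0; i < m; ++i) ws.w[i] = ws.u[i] + norm_rand();
    ws.bsolve(m);                          // theta = L'^-1 (u + e) ~ N(A^-1 b, A^-1)
    mu = ws.w[0];
    beta.assign(k, 0.0);
    for (int a = 0; a < k; ++a) beta[a] = ws.w[a + 1];
  }
};

} // namespace

// [[Rcpp::export(name = ".bvs_mcmc_cpp")]]
List bvs_mcmc_cpp(const arma::mat& X, const arma::vec& y, bool binary,
                  const arma::vec& snp_var,
                  double h_min, double h_max,
                  double l10pi_min, double l10pi_max,
                  int max_model_size, double intercept_var,
                  int n_iter, int burn_in, int thin,
                  NumericVector h_grid,
                  double h_prop_sd, double pi_prop_sd,
                  List init, bool save_state) {
  const int n = (int)X.n_rows;
  const int p = (int)X.n_cols;
  RNGScope scope;
  Engine eng(X, snp_var, intercept_var, max_model_size);

  // --- state ---
  std::vector<int> incl;
  std::vector<char> in_model(p, 0);
  double h = h_grid.size() > 0
      ? h_grid[(int)(unif_rand() * h_grid.size())]
      : h_min + unif_rand() * (h_max - h_min);
  double l10pi = l10pi_min + unif_rand() * (l10pi_max - l10pi_min);
  std::vector<double> z;
  double mu = 0.0;
  std::vector<double> beta;

  if (init.containsElementNamed("gamma")) {
    IntegerVector g0 = init["gamma"];                // 0-based
    for (int j : g0) { incl.push_back(j); in_model[j] = 1; }
  }
  if (init.containsElementNamed("h")) h = as<double>(init["h"]);
  if (init.containsElementNamed("log10_pi")) l10pi = as<double>(init["log10_pi"]);

  std::vector<double> resp(n);
  if (binary) {
    z.resize(n);
    if (init.containsElementNamed("z")) {
      NumericVector z0 = init["z"];
      for (int i = 0; i < n; ++i) z[i] = z0[i];
    } else {
      for (int i = 0; i < n; ++i) z[i] = y(i) > 0.5 ? 0.5 : -0.5;
    }
    resp = z;
  } else {
    for (int i = 0; i < n; ++i) resp[i] = y(i);
  }

  auto recompute_resp_stats = [&](double& rr, double& wtr0,
                                  std::vector<double>& wtr) {
    rr = 0.0; wtr0 = 0.0;
    for (int i = 0; i < n; ++i) { rr += resp[i] * resp[i]; wtr0 += resp[i]; }
    wtr.resize(incl.size());
    for (size_t a = 0; a < incl.size(); ++a)
      wtr[a] = eng.dot_col(incl[a], resp.data());
  };
  double rr, wtr0;
  std::vector<double> wtr;
  recompute_resp_stats(rr, wtr0, wtr);
  double cur_ml = eng.logml(incl, h, wtr0, wtr.data(), rr);

  // --- accumulators ---
  std::vector<double> pip_count(p, 0.0), beta_sum(p, 0.0);
  double mu_sum = 0.0;
  long n_pip = 0, n_coef = 0;
  int n_keep = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin : 0;
  NumericVector tr_h(n_keep), tr_pi(n_keep), tr_k(n_keep), tr_lj(n_keep);
  int keep_i = 0;
  IntegerVector prop(5), acc(5);     // add, remove, switch, h, pi
  std::vector<double> wtr2(max_model_size + 2);
  std::vector<int> incl2;
  std::vector<double> mvec(n);

  for (int iter = 0; iter < n_iter; ++iter) {
    double pi_cur = std::pow(10.0, l10pi);

    // (a) model move on gamma -------------------------------------------
    int k = (int)incl.size();
    int move = (int)(unif_rand() * 3.0);
    if (move == 0 && k < p) {                        // add
      prop[0]++;
      if (k < max_model_size) {
        int r = (int)(unif_rand() * (p - k));
        int j = -1;
        for (int c = 0, seen = 0; c < p; ++c)
          if (!in_model[c] && seen++ == r) { j = c; break; }
        incl2 = incl; incl2.push_back(j);
        for (int a = 0; a < k; ++a) wtr2[a] = wtr[a];
        wtr2[k] = eng.dot_col(j, resp.data());
        double ml2 = eng.logml(incl2, h, wtr0, wtr2.data(), rr);
        double la = ml2 - cur_ml
                  + std::log(pi_cur) - std::log1p(-pi_cur)
                  + std::log((double)(p - k)) - std::log((double)(k + 1));
        if (std::log(unif_rand()) < la) {
          incl = incl2; wtr.assign(wtr2.begin(), wtr2.begin() + k + 1);
          in_model[j] = 1; cur_ml = ml2; acc[0]++;
        }
      }
      // at the cap: the proposal to exceed it is rejected outright
    } else if (move == 1 && k > 0) {                 // remove
      prop[1]++;
      int a = (int)(unif_rand() * k);
      int j = incl[a];
      incl2 = incl; incl2.erase(incl2.begin() + a);
      for (int c = 0, w = 0; c < k; ++c) if (c != a) wtr2[w++] = wtr[c];
      double ml2 = eng.logml(incl2, h, wtr0, wtr2.data(), rr);
      double la = ml2 - cur_ml
                + std::log1p(-pi_cur) - std::log(pi_cur)
                + std::log((double)k) - std::log((double)(p - k + 1));
      if (std::log(unif_rand()) < la) {
        incl = incl2; wtr.assign(wtr2.begin(), wtr2.begin() + k - 1);
        in_model[j] = 0; cur_ml = ml2; acc[1]++;
      }
    } else if (move == 2 && k > 0 && k < p) {        // switch
      prop[2]++;
      int a = (int)(unif_rand() * k);
      int r = (int)(unif_rand() * (p - k));
      int j = -1;
      for (int c = 0, seen = 0; c < p; ++c)
        if (!in_model[c] && seen++ == r) { j = c; break; }
      int jold = incl[a];
      incl2 = incl; incl2[a] = j;
      for (int c = 0; c < k; ++c) wtr2[c] = wtr[c];
      wtr2[a] = eng.dot_col(j, resp.data());
      double ml2 = eng.logml(incl2, h, wtr0, wtr2.data(), rr);
      if (std::log(unif_rand()) < ml2 - cur_ml) {   // symmetric, prior unchanged
        incl = incl2; wtr.assign(wtr2.begin(), wtr2.begin() + k);
        in_model[jold] = 0; in_model[j] = 1;
        cur_ml = ml2; acc[2]++;
      }
    }
    k = (int)incl.size();

    // (b) h and log10 pi updates ----------------------------------------
    prop[3]++;
    {
      double h2 = h_grid.size() > 0
          ? h_grid[(int)(unif_rand() * h_grid.size())]
          : reflect_into(h + h_prop_sd * norm_rand(), h_min, h_max);
      double ml2 = (k == 0) ? cur_ml
          : eng.logml(incl, h2, wtr0, wtr.data(), rr);
      if (std::log(unif_rand()) < ml2 - cur_ml) { h = h2; cur_ml = ml2; acc[3]++; }
    }
    prop[4]++;
    {
      double l2 = reflect_into(l10pi + pi_prop_sd * norm_rand(),
                               l10pi_min, l10pi_max);
      double pi2 = std::pow(10.0, l2);
      double la = k * (std::log(pi2) - std::log(pi_cur))
                + (p - k) * (std::log1p(-pi2) - std::log1p(-pi_cur));
      if (std::log(unif_rand()) < la) { l10pi = l2; acc[4]++; }
    }

    // (c) probit data augmentation --------------------------------------
    bool past_burn = iter >= burn_in;
    bool at_thin = past_burn && ((iter - burn_in) % thin == 0);
    if (binary) {
      eng.draw_coefs(incl, h, wtr0, wtr.data(), mu, beta);
      for (int i = 0; i < n; ++i) mvec[i] = mu;
      for (int a = 0; a < k; ++a) {
        const double* x = X.colptr(incl[a]);
        double ba = beta[a];
        for (int i = 0; i < n; ++i) mvec[i] += ba * x[i];
      }
      for (int i = 0; i < n; ++i) {
        z[i] = rtruncnorm01(mvec[i], y(i) > 0.5);
        resp[i] = z[i];
      }
      recompute_resp_stats(rr, wtr0, wtr);
      cur_ml = eng.logml(incl, h, wtr0, wtr.data(), rr);
    } else if (at_thin) {
      // coefficients only needed for posterior-mean accumulation
      eng.draw_coefs(incl, h, wtr0, wtr.data(), mu, beta);
    }

    // --- accumulate -----------------------------------------------------
    if (past_burn) {
      for (int a = 0; a < k; ++a) pip_count[incl[a]] += 1.0;
      n_pip++;
      if (at_thin) {
        mu_sum += mu;
        for (int a = 0; a < k; ++a) beta_sum[incl[a]] += beta[a];
        n_coef++;
        double pi_now = std::pow(10.0, l10pi);
        tr_h[keep_i] = h;
        tr_pi[keep_i] = l10pi;
        tr_k[keep_i] = k;
        tr_lj[keep_i] = cur_ml + k * std::log(pi_now)
                        + (p - k) * std::log1p(-pi_now);
        keep_i++;
      }
    }
  }

  NumericVector pip(p), bmean(p);
  for (int j = 0; j < p; ++j) {
    pip[j] = pip_count[j] / std::max(1L, n_pip);
    bmean[j] = beta_sum[j] / std::max(1L, n_coef);
  }
  List out = List::create(
    _["pip"] = pip, _["beta_mean"] = bmean,
    _["mu_mean"] = mu_sum / std::max(1L, n_coef),
    _["trace_h"] = tr_h, _["trace_log10_pi"] = tr_pi,
    _["trace_model_size"] = tr_k, _["trace_log_joint"] = tr_lj,
    _["proposed"] = prop, _["accepted"] = acc);
  if (save_state) {
    IntegerVector g(incl.begin(), incl.end());
    out["state"] = List::create(
      _["gamma"] = g, _["h"] = h, _["log10_pi"] = l10pi,
      _["mu"] = mu, _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["z"] = binary ? NumericVector(z.begin(), z.end()) : NumericVector(0));
  }
  return out;
}
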