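// Metropolis-within-Gibbs samplers for the Leroux CAR disease-mapping
// models.  Adjacency is passed in compressed sparse column form (symmetric,
// so columns double as rows); eigenvalues of D - W are precomputed in R and
// cached for the rho update's log-determinant.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LP_CLAMP = 30.0;

static inline double clamp_lp(double x, int &nclamp) {
  if (x > LP_CLAMP) { ++nclamp; return LP_CLAMP; }
  if (x < -LP_CLAMP) { ++nclamp; return -LP_CLAMP; }
  return x;
}

// quadratic forms S'(D-W)S (sum over undirected edges of squared
// differences) and S'S
static void leroux_quads(const NumericVector &S, const IntegerVector &idx,
                         const IntegerVector &start, double &qedge,
                         double &qss) {
  int n = S.size();
  qedge = 0.0; qss = 0.0;
  for (int i = 0; i < n; ++i) {
    qss += S[i] * S[i];
    for (int k = start[i]; k < start[i + 1]; ++k) {
      int j = idx[k];
      if (j > i) { double d = S[i] - S[j]; qedge += d * d; }
    }
  }
}

static inline double rho_logdet_half(double rho, const NumericVector &eig) {
  double s = 0.0;
  for (int j = 0; j < eig.size(); ++j)
    s += std::log(rho * eig[j] + 1.0 - rho);
  return 0.5 * s;
}

// shared sigma2 / rho block; returns updated values in-place
struct VarState {
  double sigma2, rho;
  double step_ls, step_rho;
  int acc_ls, try_ls, acc_rho, try_rho;
};

static void update_sigma2(VarState &st, double qedge, double qss, int n,
                          int family, double pa, double pb, bool fixed) {
  if (fixed) return;
  double quad = st.rho * qedge + (1.0 - st.rho) * qss;
  if (family == 0) {
    // conjugate inverse-gamma(shape pa, scale pb) Gibbs step
    double shape = pa + 0.5 * n;
    double rate = pb + 0.5 * quad;
    double g = R::rgamma(shape, 1.0 / rate);
    st.sigma2 = 1.0 / g;
  } else {
    // half-normal(variance pa) on sigma2 itself: MH on log sigma2
    double ls = std::log(st.sigma2);
    double prop = ls + st.step_ls * norm_rand();
    double cur_lp = -0.5 * n * ls - 0.5 * quad / std::exp(ls)
      - std::exp(2.0 * ls) / (2.0 * pa) + ls;
    double prop_lp = -0.5 * n * prop - 0.5 * quad / std::exp(prop)
      - std::exp(2.0 * prop) / (2.0 * pa) + prop;
    ++st.try_ls;
    if (std::log(unif_rand()) < prop_lp - cur_lp) {
      st.sigma2 = std::exp(prop);
      ++st.acc_ls;
    }
  }
}

static void update_rho(VarState &st, double qedge, double qss,
                       const NumericVector &eig, bool fixed) {
  if (fixed) return;
  double prop = st.rho + st.step_rho * norm_rand();
  // reflect into [0, 1]
  for (int guard = 0; guard < 100 && (prop < 0.0 || prop > 1.0); ++guard) {
    if (prop < 0.0) prop = -prop;
    if (prop > 1.0) prop = 2.0 - prop;
  }
  if (prop < 0.0 || prop > 1.0) return;
  if (prop >= 1.0 - 1e-12) prop = 1.0 - 1e-12;
  double cur = rho_logdet_half(st.rho, eig)
    - (st.rho * qedge + (1.0 - st.rho) * qss) / (2.0 * st.sigma2);
  double pr = rho_logdet_half(prop, eig)
    - (prop * qedge + (1.0 - prop) * qss) / (2.0 * st.sigma2);
  ++st.try_rho;
  if (std::log(unif_rand()) < pr - cur) { st.rho = prop; ++st.acc_rho; }
}

static inline void adapt_step(double &step, int &acc, int &tries,
                              double target) {
  if (tries > 0) {
    double rate = double(acc) / tries;
    step *= std::exp(rate - target);
    step = std::min(std::max(step, 1e-5), 50.0);
  }
  acc = 0; tries = 0;
}

// [[Rcpp::export]]
List leroux_incidence_mcmc(NumericVector y, NumericVector E,
                           IntegerVector nbr_idx, IntegerVector nbr_start,
                           NumericVector eig,
                           int burn_in, int iterations, int thin,
                           double beta0_prior_var,
                           int var_family, double var_a, double var_b,
                           double rho_init, bool rho_fixed,
                           double sigma2_init, bool sigma2_fixed,
                           double beta0_init, bool beta0_fixed) {
  int n = y.size();
  int nclamp = 0;
  double sumy = 0.0, sumE = 0.0;
  for (int i = 0; i < n; ++i) { sumy += y[i]; sumE += E[i]; }
  double beta0 = beta0_fixed ? beta0_init
    : std::log(std::max(sumy, 0.5) / sumE);
  NumericVector S(n, 0.0), eS(n, 1.0), deg(n);
  for (int i = 0; i < n; ++i) deg[i] = nbr_start[i + 1] - nbr_start[i];
  double eb = std::exp(beta0);
  double sumEeS = sumE;  // sum_i E_i exp(S_i)

  VarState vs;
  vs.sigma2 = sigma2_fixed ? sigma2_init : 0.1;
  vs.rho = rho_fixed ? rho_init : 0.5;
  vs.step_ls = 0.5; vs.step_rho = 0.1;
  vs.acc_ls = vs.try_ls = vs.acc_rho = vs.try_rho = 0;

  NumericVector step_S(n, 0.5);
  IntegerVector accS(n, 0), tryS(n, 0);
  double step_b = 0.1; int accB = 0, tryB = 0;
  long accS_post = 0, tryS_post = 0, accB_post = 0, tryB_post = 0;
  long accR_post = 0, tryR_post = 0, accV_post = 0, tryV_post = 0;

  int total = burn_in + iterations;
  int nkeep = iterations / thin;
  NumericMatrix draws(nkeep, 3 + n);
  int row = 0;

  for (int iter = 1; iter <= total; ++iter) {
    bool adapting = iter <= burn_in;

    // beta0: random-walk Metropolis (likelihood collapses through sumEeS,
    // recomputed fresh to avoid incremental round-off)
    if (!beta0_fixed) {
      sumEeS = 0.0;
      for (int i = 0; i < n; ++i) sumEeS += E[i] * eS[i];
      double prop = beta0 + step_b * norm_rand();
      double cur_lp = sumy * beta0 - sumEeS * eb
        - beta0 * beta0 / (2.0 * beta0_prior_var);
      double ebp = std::exp(clamp_lp(prop, nclamp));
      double prop_lp = sumy * prop - sumEeS * ebp
        - prop * prop / (2.0 * beta0_prior_var);
      ++tryB; if (!adapting) ++tryB_post;
      if (std::log(unif_rand()) < prop_lp - cur_lp) {
        beta0 = prop; eb = ebp; ++accB; if (!adapting) ++accB_post;
      }
    }

    // single-site S updates with the Leroux full conditional as prior
    for (int i = 0; i < n; ++i) {
      double denom = vs.rho * deg[i] + 1.0 - vs.rho;
      double nsum = 0.0;
      for (int k = nbr_start[i]; k < nbr_start[i + 1]; ++k) nsum += S[nbr_idx[k]];
      double m = vs.rho * nsum / denom;
      double v = vs.sigma2 / denom;
      double prop = S[i] + step_S[i] * norm_rand();
      double eprop = std::exp(clamp_lp(prop, nclamp));
      double cur = y[i] * S[i] - E[i] * eb * eS[i]
        - (S[i] - m) * (S[i] - m) / (2.0 * v);
      double alt = y[i] * prop - E[i] * eb * eprop
        - (prop - m) * (prop - m) / (2.0 * v);
      ++tryS[i]; if (!adapting) ++tryS_post;
      if (std::log(unif_rand()) < alt - cur) {
        sumEeS += E[i] * (eprop - eS[i]);
        S[i] = prop; eS[i] = eprop;
        ++accS[i]; if (!adapting) ++accS_post;
      }
    }

    // exact Gibbs move along the (beta0 + c, S - c1) gauge direction:
    // the likelihood is invariant and the conditional of c is Gaussian
    // (hierarchical-centering sweep).  For a vague intercept prior this
    // is per-iteration re-centring of S with its mean absorbed into
    // beta0, but it remains measure-preserving under the proper Leroux
    // prior (1'Q1 = (1 - rho) n > 0).  Skipped when beta0 is fixed.
    if (!beta0_fixed) {
      double sumS = 0.0;
      for (int i = 0; i < n; ++i) sumS += S[i];
      double lam = 1.0 / beta0_prior_var + (1.0 - vs.rho) * n / vs.sigma2;
      double mu = (-beta0 / beta0_prior_var +
                   (1.0 - vs.rho) * sumS / vs.sigma2) / lam;
      double c = mu + norm_rand() / std::sqrt(lam);
      double f = std::exp(-c);
      for (int i = 0; i < n; ++i) { S[i] -= c; eS[i] *= f; }
      beta0 += c; eb = std::exp(beta0);
    }

    double qedge, qss;
    leroux_quads(S, nbr_idx, nbr_start, qedge, qss);
    int t0 = vs.try_ls, a0 = vs.acc_ls;
    update_sigma2(vs, qedge, qss, n, var_family, var_a, var_b, sigma2_fixed);
    if (!adapting) { tryV_post += vs.try_ls - t0; accV_post += vs.acc_ls - a0; }
    t0 = vs.try_rho; a0 = vs.acc_rho;
    update_rho(vs, qedge, qss, eig, rho_fixed);
    if (!adapting) { tryR_post += vs.try_rho - t0; accR_post += vs.acc_rho - a0; }

    if (adapting && iter % 50 == 0) {
      adapt_step(step_b, accB, tryB, 0.44);
      for (int i = 0; i < n; ++i) {
        int a = accS[i], t = tryS[i];
        adapt_step(step_S[i], a, t, 0.44);
        accS[i] = 0; tryS[i] = 0;
      }
      adapt_step(vs.step_ls, vs.acc_ls, vs.try_ls, 0.44);
      adapt_step(vs.step_rho, vs.acc_rho, vs.try_rho, 0.44);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      draws(row, 0) = beta0;
      draws(row, 1) = vs.sigma2;
      draws(row, 2) = vs.rho;
      for (int i = 0; i < n; ++i) draws(row, 3 + i) = S[i];
      ++row;
    }
  }

  NumericVector acc = NumericVector::create(
    _["beta0"] = tryB_post ? double(accB_post) / tryB_post : NA_REAL,
    _["S"] = tryS_post ? double(accS_post) / tryS_post : NA_REAL,
    _["sigma2"] = tryV_post ? double(accV_post) / tryV_post : NA_REAL,
    _["rho"] = tryR_post ? double(accR_post) / tryR_post : NA_REAL);
  return List::create(_["draws"] = draws, _["acceptance"] = acc,
                      _["n_clamped"] = nclamp);
}

// [[Rcpp::export]]
List leroux_survival_mcmc(NumericVector d, NumericVector y,
                          NumericVector dstar,
                          IntegerVector cell_area, IntegerVector cell_year,
                          NumericMatrix X,
                          int n_area,
                          IntegerVector nbr_idx, IntegerVector nbr_start,
                          NumericVector eig,
                          int burn_in, int iterations, int thin,
                          double alpha_prior_var, double beta_prior_var,
                          int var_family, double var_a, double var_b,
                          double rho_init, bool rho_fixed,
                          double sigma2_init, bool sigma2_fixed) {
  int ncell = d.size();
  int p = X.ncol();
  int nclamp = 0;

  // index cells by area, follow-up year, covariate
  std::vector< std::vector<int> > by_area(n_area), by_year(5), by_cov(p);
  for (int c = 0; c < ncell; ++c) {
    by_area[cell_area[c]].push_back(c);
    by_year[cell_year[c]].push_back(c);
    for (int k = 0; k < p; ++k) if (X(c, k) != 0.0) by_cov[k].push_back(c);
  }

  NumericVector alpha(5), beta(p), S(n_area, 0.0), deg(n_area);
  for (int i = 0; i < n_area; ++i) deg[i] = nbr_start[i + 1] - nbr_start[i];
  // crude initial baseline: overall excess rate
  double totd = 0.0, toty = 0.0, totds = 0.0;
  for (int c = 0; c < ncell; ++c) { totd += d[c]; toty += y[c]; totds += dstar[c]; }
  double a0 = std::log(std::max(totd - totds, 0.5) / std::max(toty, 1e-8));
  for (int t = 0; t < 5; ++t) alpha[t] = a0;

  NumericVector lp(ncell);
  for (int c = 0; c < ncell; ++c)
    lp[c] = clamp_lp(alpha[cell_year[c]] + S[cell_area[c]], nclamp);

  // per-cell log-likelihood contribution at linear predictor l
  auto cell_ll = [&](int c, double l) {
    double mu = dstar[c] + y[c] * std::exp(l);
    return d[c] * std::log(mu) - mu;
  };
  auto block_delta = [&](const std::vector<int> &cells, double delta,
                         const double *xw) {
    double dl = 0.0;
    for (size_t q = 0; q < cells.size(); ++q) {
      int c = cells[q];
      double shift = xw ? delta * xw[c] : delta;
      dl += cell_ll(c, lp[c] + shift) - cell_ll(c, lp[c]);
    }
    return dl;
  };
  auto block_apply = [&](const std::vector<int> &cells, double delta,
                         const double *xw) {
    for (size_t q = 0; q < cells.size(); ++q) {
      int c = cells[q];
      lp[c] += xw ? delta * xw[c] : delta;
    }
  };

  VarState vs;
  vs.sigma2 = sigma2_fixed ? sigma2_init : 0.1;
  vs.rho = rho_fixed ? rho_init : 0.5;
  vs.step_ls = 0.5; vs.step_rho = 0.1;
  vs.acc_ls = vs.try_ls = vs.acc_rho = vs.try_rho = 0;

  NumericVector step_a(5, 0.2), step_bt(std::max(p, 1), 0.2),
    step_S(n_area, 0.5);
  IntegerVector accA(5, 0), tryA(5, 0), accBt(std::max(p, 1), 0),
    tryBt(std::max(p, 1), 0), accS(n_area, 0), tryS(n_area, 0);
  long accA_post = 0, tryA_post = 0, accB_post = 0, tryB_post = 0;
  long accS_post = 0, tryS_post = 0, accR_post = 0, tryR_post = 0;
  long accV_post = 0, tryV_post = 0;

  int total = burn_in + iterations;
  int nkeep = iterations / thin;
  int npar = 5 + p + 2 + n_area;
  NumericMatrix draws(nkeep, npar);
  int row = 0;

  std::vector<const double *> xcol(p);
  for (int k = 0; k < p; ++k) xcol[k] = &X(0, k);

  for (int iter = 1; iter <= total; ++iter) {
    bool adapting = iter <= burn_in;

    for (int t = 0; t < 5; ++t) {
      if (by_year[t].empty()) continue;
      double delta = step_a[t] * norm_rand();
      double prop = alpha[t] + delta;
      double dl = block_delta(by_year[t], delta, nullptr)
        - (prop * prop - alpha[t] * alpha[t]) / (2.0 * alpha_prior_var);
      ++tryA[t]; if (!adapting) ++tryA_post;
      if (std::log(unif_rand()) < dl) {
        block_apply(by_year[t], delta, nullptr);
        alpha[t] = prop; ++accA[t]; if (!adapting) ++accA_post;
      }
    }

    for (int k = 0; k < p; ++k) {
      if (by_cov[k].empty()) continue;
      double delta = step_bt[k] * norm_rand();
      double prop = beta[k] + delta;
      double dl = block_delta(by_cov[k], delta, xcol[k])
        - (prop * prop - beta[k] * beta[k]) / (2.0 * beta_prior_var);
      ++tryBt[k]; if (!adapting) ++tryB_post;
      if (std::log(unif_rand()) < dl) {
        block_apply(by_cov[k], delta, xcol[k]);
        beta[k] = prop; ++accBt[k]; if (!adapting) ++accB_post;
      }
    }

    for (int i = 0; i < n_area; ++i) {
      double denom = vs.rho * deg[i] + 1.0 - vs.rho;
      double nsum = 0.0;
      for (int kk = nbr_start[i]; kk < nbr_start[i + 1]; ++kk)
        nsum += S[nbr_idx[kk]];
      double m = vs.rho * nsum / denom;
      double v = vs.sigma2 / denom;
      double delta = step_S[i] * norm_rand();
      double prop = S[i] + delta;
      double dl = block_delta(by_area[i], delta, nullptr)
        - ((prop - m) * (prop - m) - (S[i] - m) * (S[i] - m)) / (2.0 * v);
      ++tryS[i]; if (!adapting) ++tryS_post;
      if (std::log(unif_rand()) < dl) {
        block_apply(by_area[i], delta, nullptr);
        S[i] = prop; ++accS[i]; if (!adapting) ++accS_post;
      }
    }

    // exact Gibbs gauge move (alpha_t + c for all t, S - c1); the linear
    // predictor is invariant, the conditional of c Gaussian
    {
      double sumS = 0.0, suma = 0.0;
      for (int i = 0; i < n_area; ++i) sumS += S[i];
      for (int t = 0; t < 5; ++t) suma += alpha[t];
      double lam = 5.0 / alpha_prior_var +
        (1.0 - vs.rho) * n_area / vs.sigma2;
      double mu = (-suma / alpha_prior_var +
                   (1.0 - vs.rho) * sumS / vs.sigma2) / lam;
      double c = mu + norm_rand() / std::sqrt(lam);
      for (int i = 0; i < n_area; ++i) S[i] -= c;
      for (int t = 0; t < 5; ++t) alpha[t] += c;
    }

    double qedge, qss;
    leroux_quads(S, nbr_idx, nbr_start, qedge, qss);
    int t0 = vs.try_ls, aa0 = vs.acc_ls;
    update_sigma2(vs, qedge, qss, n_area, var_family, var_a, var_b,
                  sigma2_fixed);
    if (!adapting) { tryV_post += vs.try_ls - t0; accV_post += vs.acc_ls - aa0; }
    t0 = vs.try_rho; aa0 = vs.acc_rho;
    update_rho(vs, qedge, qss, eig, rho_fixed);
    if (!adapting) { tryR_post += vs.try_rho - t0; accR_post += vs.acc_rho - aa0; }

    if (adapting && iter % 50 == 0) {
      for (int t = 0; t < 5; ++t) {
        int a = accA[t], tt = tryA[t];
        adapt_step(step_a[t], a, tt, 0.44); accA[t] = 0; tryA[t] = 0;
      }
      for (int k = 0; k < p; ++k) {
        int a = accBt[k], tt = tryBt[k];
        adapt_step(step_bt[k], a, tt, 0.44); accBt[k] = 0; tryBt[k] = 0;
      }
      for (int i = 0; i < n_area; ++i) {
        int a = accS[i], tt = tryS[i];
        adapt_step(step_S[i], a, tt, 0.44); accS[i] = 0; tryS[i] = 0;
      }
      adapt_step(vs.step_ls, vs.acc_ls, vs.try_ls, 0.44);
      adapt_step(vs.step_rho, vs.acc_rho, vs.try_rho, 0.44);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int col = 0;
      for (int t = 0; t < 5; ++t) draws(row, col++) = alpha[t];
      for (int k = 0; k < p; ++k) draws(row, col++) = beta[k];
      draws(row, col++) = vs.sigma2;
      draws(row, col++) = vs.rho;
      for (int i = 0; i < n_area; ++i) draws(row, col++) = S[i];
      ++row;
    }
  }

  NumericVector acc = NumericVector::create(
    _["alpha"] = tryA_post ? double(accA_post) / tryA_post : NA_REAL,
    _["beta"] = tryB_post ? double(accB_post) / tryB_post : NA_REAL,
    _["S"] = tryS_post ? double(accS_post) / tryS_post : NA_REAL,
    _["sigma2"] = tryV_post ? double(accV_post) / tryV_post : NA_REAL,
    _["rho"] = tryR_post ? double(accR_post) / tryR_post : NA_REAL);
  return List::create(_["draws"] = draws, _["acceptance"] = acc,
                      _["n_clamped"] = nclamp);
}
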