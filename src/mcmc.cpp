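// Metropolis-within-Gibbs sampler for the time-varying haplotype model.
//
// Blocks: intercept (random-walk MH, diffuse normal prior), each spline /
// smoking / interaction / sex coefficient (random-walk MH, shared Laplace
// prior), haplotype frequencies (joint logit-stick-breaking walk with the
// transform Jacobian), inbreeding coefficient (reflected walk on its valid
// range), Laplace intensity (conjugate gamma Gibbs draw) and latent
// diplotypes (exact Gibbs draw over each individual's compatible pairs).
// Proposal scales are adapted toward a target acceptance rate during
// burn-in and frozen afterwards, preserving detailed balance for the
// retained draws.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x <= -37.0) return std::exp(x);
  if (x >= 34.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

static inline double logit_(double p) { return std::log(p / (1.0 - p)); }
static inline double inv_logit_(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// diplotype log-probability under (f, d): Eq. of the frequency model
static inline double log_dip_prob(const std::vector<double>& f, double d,
                                  int k, int kp) {
  double p;
  if (k == kp) p = d * f[k] + (1.0 - d) * f[k] * f[k];
  else p = 2.0 * (1.0 - d) * f[k] * f[kp];
  return std::log(std::max(p, 1e-300));
}

static double d_lower_bound_(const std::vector<double>& f) {
  double lo = -1.0;
  for (size_t k = 0; k < f.size(); ++k) {
    if (f[k] < 1.0) lo = std::max(lo, -f[k] / (1.0 - f[k]));
  }
  return lo;
}

// stick-breaking: v (m-1 logits) -> f (m simplex); returns log|Jacobian|
static double sticks_to_f(const std::vector<double>& v,
                          std::vector<double>& f) {
  int m = (int)v.size() + 1;
  double rem = 1.0, logJ = 0.0;
  for (int k = 0; k < m - 1; ++k) {
    double s = inv_logit_(v[k]);
    f[k] = s * rem;
    rem *= (1.0 - s);
    logJ += std::log(std::max(s, 1e-300)) +
            (double)(m - 1 - k) * std::log(std::max(1.0 - s, 1e-300));
  }
  f[m - 1] = rem;
  return logJ;
}

static void f_to_sticks(const std::vector<double>& f, std::vector<double>& v) {
  int m = (int)f.size();
  double rem = 1.0;
  for (int k = 0; k < m - 1; ++k) {
    double s = std::min(std::max(f[k] / rem, 1e-12), 1.0 - 1e-12);
    v[k] = logit_(s);
    rem *= (1.0 - s);
  }
}

struct Model {
  // data
  int n_rec, n_ind, m, nb;
  std::vector<int> y, E, S, ind;          // per record
  std::vector<std::vector<double> > B;    // per record, nb basis values
  std::vector<std::vector<int> > sup1, sup2; // per individual: pair members
  std::vector<std::vector<int> > recs;    // records of each individual
  // state
  double beta0, betaE, betaS, d, lambda;
  std::vector<double> Bc;                 // (m-1)*nb, h-major
  std::vector<double> betaEh;             // m-1
  std::vector<double> f, v;               // m, m-1
  std::vector<int> z;                     // support index per individual
  std::vector<std::vector<double> > X;    // per individual, m-1 copies
  std::vector<double> eta;                // per record
  std::vector<std::vector<int> > carrier; // per non-ref hap: records with X>0
  bool useLik;

  double genetic_part(int r, int i) const {
    double g = 0.0;
    for (int h = 0; h < m - 1; ++h) {
      double x = X[i][h];
      if (x == 0.0) continue;
      double be = 0.0;
      const std::vector<double>& br = B[r];
      const double* bc = &Bc[h * nb];
      for (int l = 0; l < nb; ++l) be += bc[l] * br[l];
      g += x * (be + betaEh[h] * (double)E[r]);
    }
    return g;
  }

  void recompute_eta() {
    for (int r = 0; r < n_rec; ++r) {
      int i = ind[r];
      eta[r] = beta0 + betaE * (double)E[r] + betaS * (double)S[r] +
               genetic_part(r, i);
    }
  }

  void rebuild_carriers() {
    for (int h = 0; h < m - 1; ++h) carrier[h].clear();
    for (int r = 0; r < n_rec; ++r) {
      int i = ind[r];
      for (int h = 0; h < m - 1; ++h)
        if (X[i][h] > 0.0) carrier[h].push_back(r);
    }
  }

  void set_X_from_z() {
    for (int i = 0; i < n_ind; ++i) {
      std::fill(X[i].begin(), X[i].end(), 0.0);
      int k = sup1[i][z[i]], kp = sup2[i][z[i]];
      if (k > 0) X[i][k - 1] += 1.0;
      if (kp > 0) X[i][kp - 1] += 1.0;
    }
  }

  double z_freq_loglik(const std::vector<double>& ff, double dd) const {
    double s = 0.0;
    for (int i = 0; i < n_ind; ++i)
      s += log_dip_prob(ff, dd, sup1[i][z[i]], sup2[i][z[i]]);
    return s;
  }
};

// generic scalar random-walk update over an affected-record set
// w(r) is the covariate multiplying the coefficient in eta
template <typename WFun>
static bool scalar_update(Model& M, double& coef, double scale,
                          const std::vector<int>& aff, WFun wfun,
                          bool laplace, double lap_lambda, double norm_sd) {
  double delta = R::norm_rand() * scale;
  double xp = coef + delta;
  double logr = 0.0;
  if (laplace) logr -= lap_lambda * (std::fabs(xp) - std::fabs(coef));
  else logr -= 0.5 * (xp * xp - coef * coef) / (norm_sd * norm_sd);
  if (M.useLik) {
    for (size_t a = 0; a < aff.size(); ++a) {
      int r = aff[a];
      double w = wfun(r);
      if (w == 0.0) continue;
      double de = w * delta;
      logr += (double)M.y[r] * de -
              (log1pexp_(M.eta[r] + de) - log1pexp_(M.eta[r]));
    }
  }
  if (std::log(R::unif_rand()) < logr) {
    coef = xp;
    if (M.useLik) {
      for (size_t a = 0; a < aff.size(); ++a) {
        int r = aff[a];
        double w = wfun(r);
        if (w != 0.0) M.eta[r] += w * delta;
      }
    }
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerVector y, IntegerVector E, IntegerVector S,
                   IntegerVector indiv, NumericMatrix Bmat, int n_indiv,
                   List supports, int m,
                   List prior, List init, List control) {
  Model M;
  M.n_rec = y.size();
  M.n_ind = n_indiv;
  M.m = m;
  M.nb = Bmat.ncol();
  M.y.assign(y.begin(), y.end());
  M.E.assign(E.begin(), E.end());
  M.S.assign(S.begin(), S.end());
  M.ind.assign(indiv.begin(), indiv.end());
  M.B.resize(M.n_rec, std::vector<double>(M.nb));
  for (int r = 0; r < M.n_rec; ++r)
    for (int l = 0; l < M.nb; ++l) M.B[r][l] = Bmat(r, l);
  M.sup1.resize(n_indiv);
  M.sup2.resize(n_indiv);
  for (int i = 0; i < n_indiv; ++i) {
    IntegerMatrix sp = supports[i];
    int s = sp.nrow();
    M.sup1[i].resize(s);
    M.sup2[i].resize(s);
    for (int q = 0; q < s; ++q) { M.sup1[i][q] = sp(q, 0); M.sup2[i][q] = sp(q, 1); }
  }
  M.recs.resize(n_indiv);
  for (int r = 0; r < M.n_rec; ++r) M.recs[M.ind[r]].push_back(r);

  const double pa = as<double>(prior["a"]);
  const double pb = as<double>(prior["b"]);
  const double beta0_sd = as<double>(prior["beta0_sd"]);

  M.beta0 = as<double>(init["beta0"]);
  NumericMatrix Bc0 = init["B"];
  M.Bc.assign((m - 1) * M.nb, 0.0);
  for (int h = 0; h < m - 1; ++h)
    for (int l = 0; l < M.nb; ++l) M.Bc[h * M.nb + l] = Bc0(h, l);
  M.betaE = as<double>(init["betaE"]);
  NumericVector bEh0 = init["betaEh"];
  M.betaEh.assign(bEh0.begin(), bEh0.end());
  M.betaS = as<double>(init["betaS"]);
  NumericVector f0 = init["f"];
  M.f.assign(f0.begin(), f0.end());
  M.d = as<double>(init["d"]);
  M.lambda = as<double>(init["lambda"]);
  IntegerVector z0 = init["z"];
  M.z.assign(z0.begin(), z0.end());

  const int n_iter = as<int>(control["n_iter"]);
  const int burnin = as<int>(control["burnin"]);
  const int thin = as<int>(control["thin"]);
  const bool adapt = as<bool>(control["adapt"]);
  const int adapt_interval = as<int>(control["adapt_interval"]);
  const double target_acc = as<double>(control["target_acc"]);
  const double init_scale = as<double>(control["init_scale"]);
  const bool fix_f = as<bool>(control["fix_f"]);
  const bool fix_d = as<bool>(control["fix_d"]);
  const bool fix_lambda = as<bool>(control["fix_lambda"]);
  const bool sample_z = as<bool>(control["sample_z"]);
  M.useLik = as<bool>(control["use_likelihood"]);

  const int nb = M.nb;
  const int ncoef = (m - 1) * nb;          // spline coefficients
  // scale slots: 0 = beta0, 1..ncoef = spline, then betaE, betaEh (m-1),
  // betaS, f, d
  const int iE = 1 + ncoef;
  const int iEh = iE + 1;
  const int iS = iEh + (m - 1);
  const int iF = iS + 1;
  const int iD = iF + 1;
  const int nscale = iD + 1;
  std::vector<double> scale(nscale, init_scale);
  scale[iF] = 0.15;
  scale[iD] = 0.1;
  std::vector<long> acc_w(nscale, 0), att_w(nscale, 0);  // adaptation window
  std::vector<long> acc_t(nscale, 0), att_t(nscale, 0);  // post-burn-in tally

  M.X.assign(n_indiv, std::vector<double>(std::max(m - 1, 0), 0.0));
  M.eta.assign(M.n_rec, 0.0);
  M.carrier.assign(std::max(m - 1, 0), std::vector<int>());
  M.v.assign(std::max(m - 1, 0), 0.0);
  if (m > 1) f_to_sticks(M.f, M.v);
  M.set_X_from_z();
  M.recompute_eta();
  M.rebuild_carriers();

  // affected-record index sets for the non-genetic scalar blocks
  std::vector<int> all_recs(M.n_rec), smoke_recs, male_recs;
  for (int r = 0; r < M.n_rec; ++r) {
    all_recs[r] = r;
    if (M.E[r] == 1) smoke_recs.push_back(r);
    if (M.S[r] == 1) male_recs.push_back(r);
  }

  const int n_keep = (burnin < n_iter) ? (n_iter - burnin) / thin : 0;
  NumericVector k_beta0(n_keep), k_betaE(n_keep), k_betaS(n_keep),
      k_d(n_keep), k_lambda(n_keep);
  NumericMatrix k_B(n_keep, ncoef), k_betaEh(n_keep, std::max(m - 1, 0)),
      k_f(n_keep, m);
  std::vector<double> fitted_acc(M.n_rec, 0.0);
  long fitted_n = 0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- intercept ---
    att_w[0]++; att_t[0]++;
    if (scalar_update(M, M.beta0, scale[0], all_recs,
                      [](int) { return 1.0; }, false, 0.0, beta0_sd)) {
      acc_w[0]++; acc_t[0]++;
    }

    // --- spline coefficients (Laplace prior) ---
    for (int h = 0; h < m - 1; ++h) {
      const std::vector<int>& aff = M.carrier[h];
      for (int l = 0; l < nb; ++l) {
        int sidx = 1 + h * nb + l;
        att_w[sidx]++; att_t[sidx]++;
        Model* pm = &M;
        int hh = h, ll = l;
        bool ok = scalar_update(
            M, M.Bc[h * nb + l], scale[sidx], aff,
            [pm, hh, ll](int r) {
              return pm->X[pm->ind[r]][hh] * pm->B[r][ll];
            },
            true, M.lambda, 0.0);
        if (ok) { acc_w[sidx]++; acc_t[sidx]++; }
      }
    }

    // --- smoking main effect ---
    att_w[iE]++; att_t[iE]++;
    if (scalar_update(M, M.betaE, scale[iE], smoke_recs,
                      [](int) { return 1.0; }, true, M.lambda, 0.0)) {
      acc_w[iE]++; acc_t[iE]++;
    }

    // --- haplotype x smoking interactions ---
    for (int h = 0; h < m - 1; ++h) {
      int sidx = iEh + h;
      att_w[sidx]++; att_t[sidx]++;
      Model* pm = &M;
      int hh = h;
      bool ok = scalar_update(
          M, M.betaEh[h], scale[sidx], M.carrier[h],
          [pm, hh](int r) {
            return (double)pm->E[r] * pm->X[pm->ind[r]][hh];
          },
          true, M.lambda, 0.0);
      if (ok) { acc_w[sidx]++; acc_t[sidx]++; }
    }

    // --- sex effect ---
    att_w[iS]++; att_t[iS]++;
    if (scalar_update(M, M.betaS, scale[iS], male_recs,
                      [](int) { return 1.0; }, true, M.lambda, 0.0)) {
      acc_w[iS]++; acc_t[iS]++;
    }

    // --- haplotype frequencies: joint stick-breaking walk ---
    if (!fix_f && m > 1) {
      att_w[iF]++; att_t[iF]++;
      std::vector<double> vp(M.v), fp(m);
      for (int k = 0; k < m - 1; ++k) vp[k] += R::norm_rand() * scale[iF];
      double logJp = sticks_to_f(vp, fp);
      bool valid = true;
      for (int k = 0; k < m; ++k) if (fp[k] < 1e-12) valid = false;
      if (valid && M.d < d_lower_bound_(fp) + 1e-8) valid = false;
      if (valid) {
        std::vector<double> fcur(M.f);
        double logJ = sticks_to_f(M.v, fcur);
        double logr = logJp - logJ;
        if (M.useLik)
          logr += M.z_freq_loglik(fp, M.d) - M.z_freq_loglik(M.f, M.d);
        if (std::log(R::unif_rand()) < logr) {
          M.v = vp; M.f = fp;
          acc_w[iF]++; acc_t[iF]++;
        }
      }
    }

    // --- inbreeding coefficient: reflected walk on its valid range ---
    if (!fix_d) {
      double lo = d_lower_bound_(M.f) + 1e-8, hi = 1.0 - 1e-8;
      if (lo < hi) {
        att_w[iD]++; att_t[iD]++;
        double dp = M.d + R::norm_rand() * scale[iD];
        for (int rep = 0; rep < 100 && (dp < lo || dp > hi); ++rep) {
          if (dp < lo) dp = 2.0 * lo - dp;
          if (dp > hi) dp = 2.0 * hi - dp;
        }
        if (dp >= lo && dp <= hi) {
          double logr = M.useLik ?
              (M.z_freq_loglik(M.f, dp) - M.z_freq_loglik(M.f, M.d)) : 0.0;
          if (std::log(R::unif_rand()) < logr) {
            M.d = dp;
            acc_w[iD]++; acc_t[iD]++;
          }
        }
      }
    }

    // --- Laplace intensity: conjugate gamma Gibbs draw ---
    if (!fix_lambda) {
      double sumabs = std::fabs(M.betaE) + std::fabs(M.betaS);
      for (int c = 0; c < ncoef; ++c) sumabs += std::fabs(M.Bc[c]);
      for (int h = 0; h < m - 1; ++h) sumabs += std::fabs(M.betaEh[h]);
      int K = ncoef + (m - 1) + 2;
      M.lambda = R::rgamma(pa + (double)K, 1.0 / (pb + sumabs));
    }

    // --- latent diplotypes: exact Gibbs over each support ---
    if (sample_z && M.useLik) {
      bool changed = false;
      for (int i = 0; i < n_indiv; ++i) {
        int s = (int)M.sup1[i].size();
        if (s == 1) continue;
        std::vector<double> lw(s);
        double mx = -1e300;
        for (int q = 0; q < s; ++q) {
          int k = M.sup1[i][q], kp = M.sup2[i][q];
          double w = log_dip_prob(M.f, M.d, k, kp);
          for (size_t a = 0; a < M.recs[i].size(); ++a) {
            int r = M.recs[i][a];
            double g = 0.0;
            int hs[2] = { k, kp };
            for (int u = 0; u < 2; ++u) {
              int hh = hs[u];
              if (hh == 0) continue;
              double be = 0.0;
              const double* bc = &M.Bc[(hh - 1) * nb];
              for (int l = 0; l < nb; ++l) be += bc[l] * M.B[r][l];
              g += be + M.betaEh[hh - 1] * (double)M.E[r];
            }
            double e = M.beta0 + M.betaE * (double)M.E[r] +
                       M.betaS * (double)M.S[r] + g;
            w += (double)M.y[r] * e - log1pexp_(e);
          }
          lw[q] = w;
          if (w > mx) mx = w;
        }
        double tot = 0.0;
        for (int q = 0; q < s; ++q) { lw[q] = std::exp(lw[q] - mx); tot += lw[q]; }
        double u = R::unif_rand() * tot, c = 0.0;
        int pick = s - 1;
        for (int q = 0; q < s; ++q) { c += lw[q]; if (u <= c) { pick = q; break; } }
        if (pick != M.z[i]) changed = true;
        M.z[i] = pick;
      }
      if (changed) {
        M.set_X_from_z();
        M.recompute_eta();
        M.rebuild_carriers();
      }
    }

    // --- adaptation (burn-in only) ---
    if (adapt && it <= burnin && it % adapt_interval == 0) {
      for (int sdx = 0; sdx < nscale; ++sdx) {
        if (att_w[sdx] == 0) continue;
        double rate = (double)acc_w[sdx] / (double)att_w[sdx];
        scale[sdx] *= std::exp(rate - target_acc);
        scale[sdx] = std::min(std::max(scale[sdx], 1e-4), 100.0);
        acc_w[sdx] = att_w[sdx] = 0;
      }
      // restart post-burn-in tallies so reported rates are post-adaptation
      std::fill(acc_t.begin(), acc_t.end(), 0);
      std::fill(att_t.begin(), att_t.end(), 0);
    }

    // --- storage ---
    if (it > burnin) {
      if (M.useLik) {
        for (int r = 0; r < M.n_rec; ++r)
          fitted_acc[r] += 1.0 / (1.0 + std::exp(-M.eta[r]));
        fitted_n++;
      }
      if ((it - burnin) % thin == 0 && kept < n_keep) {
        k_beta0[kept] = M.beta0;
        for (int c = 0; c < ncoef; ++c) k_B(kept, c) = M.Bc[c];
        k_betaE[kept] = M.betaE;
        for (int h = 0; h < m - 1; ++h) k_betaEh(kept, h) = M.betaEh[h];
        k_betaS[kept] = M.betaS;
        for (int k = 0; k < m; ++k) k_f(kept, k) = M.f[k];
        k_d[kept] = M.d;
        k_lambda[kept] = M.lambda;
        kept++;
      }
    }
  }

  NumericVector fitted(M.n_rec);
  if (fitted_n > 0)
    for (int r = 0; r < M.n_rec; ++r) fitted[r] = fitted_acc[r] / (double)fitted_n;

  NumericVector acc_rate(nscale), att_out(nscale), scale_out(nscale);
  for (int sdx = 0; sdx < nscale; ++sdx) {
    acc_rate[sdx] = att_t[sdx] > 0 ? (double)acc_t[sdx] / (double)att_t[sdx]
                                   : NA_REAL;
    att_out[sdx] = (double)att_t[sdx];
    scale_out[sdx] = scale[sdx];
  }

  IntegerVector z_last(n_indiv);
  for (int i = 0; i < n_indiv; ++i) z_last[i] = M.z[i];

  return List::create(
      _["beta0"] = k_beta0, _["B"] = k_B, _["betaE"] = k_betaE,
      _["betaEh"] = k_betaEh, _["betaS"] = k_betaS, _["f"] = k_f,
      _["d"] = k_d, _["lambda"] = k_lambda, _["fitted"] = fitted,
      _["acceptance"] = acc_rate, _["attempts"] = att_out,
      _["scales"] = scale_out, _["z_last"] = z_last, _["n_kept"] = kept);
}
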