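// Metropolis-within-Gibbs sampler for (spatial) hierarchical zero-inflated
// count models. Fixed effects and latent district effects move by adaptive
// random-walk MH; variance components use conjugate Gamma/Wishart updates.
// All randomness comes from R's RNG, so set.seed() governs reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// family codes: 0 poisson, 1 nb, 2 zip, 3 zinb
// effects codes: 0 none, 1 independent, 2 shared, 3 correlated
// spatial codes: 0 none, 1 icar, 2 proper, 3 bicar

static inline double zl_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double obs_ll(double y, double etaz, double etac,
                            int family, double r) {
  double lp0; // log f(y) under the count distribution
  if (family == 0 || family == 2) { // Poisson, mean exp(etac)
    lp0 = y * etac - std::exp(etac) - std::lgamma(y + 1.0);
  } else {                          // NB, mean exp(etac), size r
    double nu = std::exp(etac);
    lp0 = std::lgamma(y + r) - std::lgamma(r) - std::lgamma(y + 1.0)
        + r * std::log(r / (r + nu));
    if (y > 0) lp0 += y * (etac - std::log(r + nu));
  }
  if (family == 0 || family == 1) return lp0;
  double log_pi = -zl_log1pexp(-etaz);
  double log_1mpi = -zl_log1pexp(etaz);
  if (y == 0.0) {
    double a = log_pi, b = log_1mpi + lp0;
    double mx = (a > b) ? a : b;
    return mx + std::log(std::exp(a - mx) + std::exp(b - mx));
  }
  return log_1mpi + lp0;
}

// Wishart draw, standard notation: E[W] = df * V. Bartlett, p = 2.
static arma::mat rwishart2(double df, const arma::mat& V) {
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

struct AdaptStep {
  double s;
  int acc, tries;
  AdaptStep() : s(0.5), acc(0), tries(0) {}
  void tally(bool a) { tries++; if (a) acc++; }
  void adapt() { // called every batch during burn-in; target 0.44
    if (tries == 0) return;
    double rate = (double)acc / tries;
    if (rate > 0.44) s *= 1.1; else s *= 0.9;
    if (s < 1e-4) s = 1e-4;
    if (s > 20.0) s = 20.0;
    acc = 0; tries = 0;
  }
};

// [[Rcpp::export(name = ".zi_mcmc_cpp")]]
List zi_mcmc_cpp(const arma::vec& y,
                 const arma::mat& X,
                 const arma::mat& Z,
                 const arma::vec& offset,
                 const arma::ivec& district,   // 0-based, length n
                 int ndist,
                 List nb,                      // 0-based neighbour lists
                 const arma::vec& m,           // neighbour counts
                 const arma::imat& edges,      // 0-based, E x 2
                 const arma::ivec& count_swap,  // X dummy-block cols (0-based)
                 const arma::ivec& zero_swap,   // Z dummy-block cols (0-based)
                 const arma::vec& gamma_eigs,  // eigenvalues for proper CAR
                 double psi_lo, double psi_hi,
                 int family, int effects, int spatial,
                 int coef_scope,               // 0 shared, 1 per-coefficient
                 List priors,
                 int iterations, int burnin, int thin,
                 List init,
                 bool prior_only) {
  const int n = y.n_elem;
  const int qb = X.n_cols;
  const bool zi = (family >= 2);
  const int qa = zi ? Z.n_cols : 0;
  const bool nbfam = (family == 1 || family == 3);

  // priors
  arma::vec ab_beta = priors["beta_prec_gamma"];
  arma::vec ab_alpha = priors["alpha_prec_gamma"];
  arma::vec ab_re = priors["re_prec_gamma"];
  arma::vec ab_car = priors["car_prec_gamma"];
  arma::vec ab_r = priors["r_gamma"];
  double zeta_prec = priors["zeta_prec"];
  double wdf = priors["wishart_df"];
  arma::mat womega = priors["wishart_scale"];
  bool fix_bprec = !Rf_isNull(priors["beta_prec_fixed"]);
  bool fix_aprec = !Rf_isNull(priors["alpha_prec_fixed"]);
  double bprec_fix = fix_bprec ? Rcpp::as<double>(priors["beta_prec_fixed"]) : 0.0;
  double aprec_fix = fix_aprec ? Rcpp::as<double>(priors["alpha_prec_fixed"]) : 0.0;

  // shared fixed-effect prior variances (coef_scope == 0), Gibbs-updated
  double sig2_bsh = 10.0, sig2_ash = 10.0;

  // state
  arma::vec beta = init["beta"];
  arma::vec alpha = zi ? Rcpp::as<arma::vec>(init["alpha"]) : arma::vec();
  arma::vec theta = init["theta"];
  arma::vec vartheta = init["vartheta"];
  arma::vec u1 = init["u1"];
  arma::vec u2 = init["u2"];
  double sig2_theta = init["sig2_theta"];
  double sig2_vt = init["sig2_vartheta"];
  double rho = init["rho"];
  double zeta = init["zeta"];
  double sig2_u = init["sig2_u"];
  arma::mat Sig_u = init["Sigma_u"];
  double psi = init["psi"];
  double r = init["r"];

  const bool use_theta = (effects != 0);
  const bool use_vt = (effects == 1 || effects == 3) && zi;
  const bool shared = (effects == 2);
  const bool corr = (effects == 3);
  if (shared) vartheta = zeta * theta;

  // facilities per district; nonzero rows per design column
  std::vector< std::vector<int> > dfac(ndist);
  for (int k = 0; k < n; k++) dfac[district[k]].push_back(k);
  std::vector< std::vector<int> > xnz(qb), znz(qa);
  for (int c = 0; c < qb; c++)
    for (int k = 0; k < n; k++) if (X(k, c) != 0.0) xnz[c].push_back(k);
  for (int c = 0; c < qa; c++)
    for (int k = 0; k < n; k++) if (Z(k, c) != 0.0) znz[c].push_back(k);

  // reference rows of the swap blocks: rows where every block dummy is 0
  std::vector<int> count_ref, zero_ref;
  for (int k = 0; k < n; k++) {
    bool ref = true;
    for (unsigned int t = 0; t < count_swap.n_elem; t++)
      if (X(k, count_swap[t]) != 0.0) { ref = false; break; }
    if (ref && count_swap.n_elem > 0) count_ref.push_back(k);
  }
  for (int k = 0; k < n; k++) {
    bool ref = true;
    for (unsigned int t = 0; t < zero_swap.n_elem; t++)
      if (Z(k, zero_swap[t]) != 0.0) { ref = false; break; }
    if (ref && zero_swap.n_elem > 0) zero_ref.push_back(k);
  }

  // neighbour lists as vectors
  std::vector< std::vector<int> > nbv(ndist);
  for (int i = 0; i < ndist; i++) {
    IntegerVector v = nb[i];
    nbv[i] = std::vector<int>(v.begin(), v.end());
  }
  const int nedge = edges.n_rows;

  // linear predictors and per-observation loglik cache
  arma::vec etaC = X * beta + offset;
  for (int k = 0; k < n; k++) etaC[k] += theta[district[k]] + u2[district[k]];
  arma::vec etaZ(n, arma::fill::zeros);
  if (zi) {
    etaZ = Z * alpha;
    for (int k = 0; k < n; k++) etaZ[k] += vartheta[district[k]] + u1[district[k]];
  }
  arma::vec llv(n, arma::fill::zeros);
  auto refresh_ll = [&](void) {
    if (prior_only) { llv.zeros(); return; }
    for (int k = 0; k < n; k++) llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
  };
  refresh_ll();

  // adaptive steps
  std::vector<AdaptStep> st_beta(qb), st_alpha(std::max(qa, 1)),
      st_theta(ndist), st_vt(ndist), st_u1(ndist), st_u2(ndist);
  AdaptStep st_zeta, st_psi, st_logr;
  AdaptStep st_swapC, st_swapZ, st_lvlT, st_lvlV;
  st_psi.s = 0.2; st_logr.s = 0.3;

  const int nkeep = (iterations - burnin + thin - 1) / thin;
  arma::mat S_beta(nkeep, qb), S_alpha(nkeep, std::max(qa, 0));
  arma::mat S_theta(nkeep, use_theta ? ndist : 0);
  arma::mat S_vt(nkeep, (use_vt || shared) ? ndist : 0);
  arma::mat S_u1(nkeep, (spatial == 3) ? ndist : 0);
  arma::mat S_u2(nkeep, (spatial != 0) ? ndist : 0);
  arma::mat S_scal(nkeep, 10); // sig2_theta sig2_vt rho zeta sig2_u1 sig2_u2 sig12 psi phi deviance
  int keep = 0;

  // prior log-ratio helpers. Fixed effects with a Gamma(a, b) precision
  // hyperprior use the collapsed (marginalised) prior: p(coef) propto
  // (b + coef^2/2)^-(a + 1/2), a scaled t kernel. Marginalising removes the
  // spike-induced stickiness of alternating coef/precision Gibbs while
  // leaving the posterior of coef unchanged.
  auto lpr_gauss = [](double prop, double cur, double mean, double var) {
    return -0.5 * ((prop - mean) * (prop - mean)
                 - (cur - mean) * (cur - mean)) / var;
  };
  auto lpr_fixef = [&](double prop, double cur, const arma::vec& ab,
                       bool fixed, double prec, double sh_var) {
    if (fixed) return -0.5 * prec * (prop * prop - cur * cur);
    if (coef_scope == 0) return -0.5 * (prop * prop - cur * cur) / sh_var;
    return -(ab[0] + 0.5) * (std::log(ab[1] + 0.5 * prop * prop)
                           - std::log(ab[1] + 0.5 * cur * cur));
  };

  // RW-MH for one scalar component, likelihood over idx; prior log-ratio
  // supplied. delta applied to etaC (which==0) or etaZ (which==1).
  auto mh_scalar = [&](double cur, double prior_lr,
                       const std::vector<int>& idx, const arma::vec* wcol,
                       int which, double prop, AdaptStep& stp,
                       bool& accepted) -> double {
    double lr = prior_lr;
    double d = prop - cur;
    if (!prior_only) {
      for (size_t t = 0; t < idx.size(); t++) {
        int k = idx[t];
        double w = wcol ? (*wcol)[k] : 1.0;
        double ez = etaZ[k] + ((which == 1) ? d * w : 0.0);
        double ec = etaC[k] + ((which == 0) ? d * w : 0.0);
        lr += obs_ll(y[k], ez, ec, family, r) - llv[k];
      }
    }
    accepted = (std::log(R::unif_rand()) < lr);
    stp.tally(accepted);
    if (accepted) {
      for (size_t t = 0; t < idx.size(); t++) {
        int k = idx[t];
        double w = wcol ? (*wcol)[k] : 1.0;
        if (which == 1) etaZ[k] += d * w; else etaC[k] += d * w;
        if (!prior_only)
          llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
      }
      return prop;
    }
    return cur;
  };

  std::vector<int> allidx(n);
  for (int k = 0; k < n; k++) allidx[k] = k;

  for (int it = 0; it < iterations; it++) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    bool acc;

    // ---- fixed effects, count component ----
    for (int c = 0; c < qb; c++) {
      arma::vec col = X.col(c);
      double prop = beta[c] + st_beta[c].s * R::norm_rand();
      double plr = lpr_fixef(prop, beta[c], ab_beta, fix_bprec, bprec_fix,
                             sig2_bsh);
      beta[c] = mh_scalar(beta[c], plr, xnz[c], &col, 0, prop,
                          st_beta[c], acc);
    }
    // ---- fixed effects, zero component ----
    if (zi) {
      for (int c = 0; c < qa; c++) {
        arma::vec col = Z.col(c);
        double prop = alpha[c] + st_alpha[c].s * R::norm_rand();
        double plr = lpr_fixef(prop, alpha[c], ab_alpha, fix_aprec,
                               aprec_fix, sig2_ash);
        alpha[c] = mh_scalar(alpha[c], plr, znz[c], &col, 1, prop,
                             st_alpha[c], acc);
      }
    }

    if (coef_scope == 0 && !fix_bprec) {
      double shape = ab_beta[0] + 0.5 * qb;
      double rate = ab_beta[1] + 0.5 * arma::dot(beta, beta);
      sig2_bsh = 1.0 / R::rgamma(shape, 1.0 / rate);
    }
    if (zi && coef_scope == 0 && !fix_aprec) {
      double shape = ab_alpha[0] + 0.5 * qa;
      double rate = ab_alpha[1] + 0.5 * arma::dot(alpha, alpha);
      sig2_ash = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // ---- non-spatial district intercepts ----
    if (use_theta && !shared) {
      for (int i = 0; i < ndist; i++) {
        double pm = 0.0, pv = sig2_theta;
        if (corr) {
          double sv = std::sqrt(sig2_vt), stt = std::sqrt(sig2_theta);
          pm = rho * stt / sv * vartheta[i];
          pv = sig2_theta * (1.0 - rho * rho);
        }
        double prop = theta[i] + st_theta[i].s * R::norm_rand();
        theta[i] = mh_scalar(theta[i], lpr_gauss(prop, theta[i], pm, pv),
                             dfac[i], nullptr, 0, prop, st_theta[i], acc);
      }
      if (use_vt) {
        for (int i = 0; i < ndist; i++) {
          double pm = 0.0, pv = sig2_vt;
          if (corr) {
            double sv = std::sqrt(sig2_vt), stt = std::sqrt(sig2_theta);
            pm = rho * sv / stt * theta[i];
            pv = sig2_vt * (1.0 - rho * rho);
          }
          double prop = vartheta[i] + st_vt[i].s * R::norm_rand();
          vartheta[i] = mh_scalar(vartheta[i],
                                  lpr_gauss(prop, vartheta[i], pm, pv),
                                  dfac[i], nullptr, 1, prop, st_vt[i], acc);
        }
      }
      if (corr) {
        arma::mat S(2, 2, arma::fill::zeros);
        for (int i = 0; i < ndist; i++) {
          arma::vec v = {theta[i], vartheta[i]};
          S += v * v.t();
        }
        arma::mat P = rwishart2(wdf + ndist, arma::inv_sympd(womega + S));
        arma::mat Sg = arma::inv_sympd(P);
        sig2_theta = Sg(0, 0); sig2_vt = Sg(1, 1);
        rho = Sg(0, 1) / std::sqrt(Sg(0, 0) * Sg(1, 1));
      } else {
        double shape = ab_re[0] + 0.5 * ndist;
        double rate = ab_re[1] + 0.5 * arma::dot(theta, theta);
        sig2_theta = 1.0 / R::rgamma(shape, 1.0 / rate);
        if (use_vt) {
          rate = ab_re[1] + 0.5 * arma::dot(vartheta, vartheta);
          sig2_vt = 1.0 / R::rgamma(shape, 1.0 / rate);
        }
      }
    } else if (shared) {
      // one latent intercept drives both components: vartheta = zeta * theta
      for (int i = 0; i < ndist; i++) {
        double cur = theta[i];
        double prop = cur + st_theta[i].s * R::norm_rand();
        double d = prop - cur;
        double lr = -0.5 * (prop * prop - cur * cur) / sig2_theta;
        if (!prior_only) {
          for (int k : dfac[i]) {
            double ez = etaZ[k] + (zi ? zeta * d : 0.0);
            double ec = etaC[k] + d;
            lr += obs_ll(y[k], ez, ec, family, r) - llv[k];
          }
        }
        bool a = (std::log(R::unif_rand()) < lr);
        st_theta[i].tally(a);
        if (a) {
          theta[i] = prop;
          vartheta[i] = zeta * prop;
          for (int k : dfac[i]) {
            if (zi) etaZ[k] += zeta * d;
            etaC[k] += d;
            if (!prior_only)
              llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
          }
        }
      }
      if (zi) { // proportionality constant
        double cur = zeta;
        double prop = cur + st_zeta.s * R::norm_rand();
        double lr = -0.5 * zeta_prec * (prop * prop - cur * cur);
        if (!prior_only) {
          for (int k = 0; k < n; k++) {
            double ez = etaZ[k] + (prop - cur) * theta[district[k]];
            lr += obs_ll(y[k], ez, etaC[k], family, r) - llv[k];
          }
        }
        bool a = (std::log(R::unif_rand()) < lr);
        st_zeta.tally(a);
        if (a) {
          for (int k = 0; k < n; k++) {
            etaZ[k] += (prop - cur) * theta[district[k]];
            if (!prior_only)
              llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
          }
          zeta = prop;
          vartheta = zeta * theta;
        }
      }
      double shape = ab_re[0] + 0.5 * ndist;
      double rate = ab_re[1] + 0.5 * arma::dot(theta, theta);
      sig2_theta = 1.0 / R::rgamma(shape, 1.0 / rate);
      sig2_vt = zeta * zeta * sig2_theta;
    }

    // ---- spatial fields ----
    if (spatial == 1 || spatial == 2) { // univariate CAR in count component
      for (int i = 0; i < ndist; i++) {
        if (m[i] == 0) continue; // pinned island
        double nbavg = 0.0;
        for (int j : nbv[i]) nbavg += u2[j];
        nbavg /= m[i];
        double pm = (spatial == 2 ? psi : 1.0) * nbavg;
        double pv = sig2_u / m[i];
        double prop = u2[i] + st_u2[i].s * R::norm_rand();
        u2[i] = mh_scalar(u2[i], lpr_gauss(prop, u2[i], pm, pv),
                          dfac[i], nullptr, 0, prop, st_u2[i], acc);
      }
      if (spatial == 1) {
        // likelihood-preserving recentring: the ICAR kernel is shift
        // invariant, the shift is absorbed by the count intercept
        int nf = 0; double c = 0.0;
        for (int i = 0; i < ndist; i++) if (m[i] > 0) { c += u2[i]; nf++; }
        c /= nf;
        for (int i = 0; i < ndist; i++) if (m[i] > 0) u2[i] -= c;
        beta[0] += c;
        double q = 0.0;
        for (int e = 0; e < nedge; e++) {
          double d = u2[edges(e, 0)] - u2[edges(e, 1)];
          q += d * d;
        }
        double shape = ab_car[0] + 0.5 * (nf - 1);
        double rate = ab_car[1] + 0.5 * q;
        sig2_u = 1.0 / R::rgamma(shape, 1.0 / rate);
      } else { // proper CAR
        double quadD = 0.0, quadW = 0.0;
        for (int i = 0; i < ndist; i++) quadD += m[i] * u2[i] * u2[i];
        for (int e = 0; e < nedge; e++)
          quadW += 2.0 * u2[edges(e, 0)] * u2[edges(e, 1)];
        double shape = ab_car[0] + 0.5 * ndist;
        double rate = ab_car[1] + 0.5 * (quadD - psi * quadW);
        sig2_u = 1.0 / R::rgamma(shape, 1.0 / rate);
        // psi: uniform prior on (psi_lo, psi_hi), RW-MH
        double prop = psi + st_psi.s * R::norm_rand();
        if (prop > psi_lo && prop < psi_hi) {
          double lr = 0.0;
          for (unsigned int l = 0; l < gamma_eigs.n_elem; l++)
            lr += 0.5 * (std::log1p(-prop * gamma_eigs[l])
                       - std::log1p(-psi * gamma_eigs[l]));
          lr += 0.5 * (prop - psi) * quadW / sig2_u;
          bool a = (std::log(R::unif_rand()) < lr);
          st_psi.tally(a);
          if (a) psi = prop;
        } else st_psi.tally(false);
      }
    } else if (spatial == 3) { // bivariate intrinsic CAR
      double s11 = Sig_u(0, 0), s22 = Sig_u(1, 1), s12 = Sig_u(0, 1);
      for (int i = 0; i < ndist; i++) {
        if (m[i] == 0) continue;
        double b1 = 0.0, b2 = 0.0;
        for (int j : nbv[i]) { b1 += u1[j]; b2 += u2[j]; }
        b1 /= m[i]; b2 /= m[i];
        // u1_i | u2_i, neighbours
        double pm = b1 + (s12 / s22) * (u2[i] - b2);
        double pv = (s11 - s12 * s12 / s22) / m[i];
        double prop1 = u1[i] + st_u1[i].s * R::norm_rand();
        u1[i] = mh_scalar(u1[i], lpr_gauss(prop1, u1[i], pm, pv),
                          dfac[i], nullptr, 1, prop1, st_u1[i], acc);
        // u2_i | u1_i, neighbours
        pm = b2 + (s12 / s11) * (u1[i] - b1);
        pv = (s22 - s12 * s12 / s11) / m[i];
        double prop2 = u2[i] + st_u2[i].s * R::norm_rand();
        u2[i] = mh_scalar(u2[i], lpr_gauss(prop2, u2[i], pm, pv),
                          dfac[i], nullptr, 0, prop2, st_u2[i], acc);
      }
      int nf = 0; double c1 = 0.0, c2 = 0.0;
      for (int i = 0; i < ndist; i++) if (m[i] > 0) { c1 += u1[i]; c2 += u2[i]; nf++; }
      c1 /= nf; c2 /= nf;
      for (int i = 0; i < ndist; i++) if (m[i] > 0) { u1[i] -= c1; u2[i] -= c2; }
      alpha[0] += c1; beta[0] += c2;
      arma::mat S(2, 2, arma::fill::zeros);
      for (int e = 0; e < nedge; e++) {
        arma::vec d = {u1[edges(e, 0)] - u1[edges(e, 1)],
                       u2[edges(e, 0)] - u2[edges(e, 1)]};
        S += d * d.t();
      }
      arma::mat P = rwishart2(wdf + nf - 1, arma::inv_sympd(womega + S));
      Sig_u = arma::inv_sympd(P);
    }

    // ---- ridge (block) moves ----
    // The componentwise sampler mixes slowly along two soft directions:
    // (intercept vs a dummy block whose reference cell is rare) and
    // (intercept vs the common level of the district intercepts). These
    // joint proposals move along those directions; both are ordinary MH
    // moves and leave the posterior invariant.
    if (count_swap.n_elem > 0) { // beta0 += d, block -= d
      double dlt = st_swapC.s * R::norm_rand();
      double lr = lpr_fixef(beta[0] + dlt, beta[0], ab_beta, fix_bprec,
                            bprec_fix, sig2_bsh);
      for (unsigned int t = 0; t < count_swap.n_elem; t++)
        lr += lpr_fixef(beta[count_swap[t]] - dlt, beta[count_swap[t]],
                        ab_beta, fix_bprec, bprec_fix, sig2_bsh);
      if (!prior_only)
        for (int k : count_ref)
          lr += obs_ll(y[k], etaZ[k], etaC[k] + dlt, family, r) - llv[k];
      bool a = (std::log(R::unif_rand()) < lr);
      st_swapC.tally(a);
      if (a) {
        beta[0] += dlt;
        for (unsigned int t = 0; t < count_swap.n_elem; t++)
          beta[count_swap[t]] -= dlt;
        for (int k : count_ref) {
          etaC[k] += dlt;
          if (!prior_only) llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
        }
      }
    }
    if (zi && zero_swap.n_elem > 0) { // alpha0 += d, block -= d
      double dlt = st_swapZ.s * R::norm_rand();
      double lr = lpr_fixef(alpha[0] + dlt, alpha[0], ab_alpha, fix_aprec,
                            aprec_fix, sig2_ash);
      for (unsigned int t = 0; t < zero_swap.n_elem; t++)
        lr += lpr_fixef(alpha[zero_swap[t]] - dlt, alpha[zero_swap[t]],
                        ab_alpha, fix_aprec, aprec_fix, sig2_ash);
      if (!prior_only)
        for (int k : zero_ref)
          lr += obs_ll(y[k], etaZ[k] + dlt, etaC[k], family, r) - llv[k];
      bool a = (std::log(R::unif_rand()) < lr);
      st_swapZ.tally(a);
      if (a) {
        alpha[0] += dlt;
        for (unsigned int t = 0; t < zero_swap.n_elem; t++)
          alpha[zero_swap[t]] -= dlt;
        for (int k : zero_ref) {
          etaZ[k] += dlt;
          if (!prior_only) llv[k] = obs_ll(y[k], etaZ[k], etaC[k], family, r);
        }
      }
    }
    if (use_theta) { // beta0 += d, theta -= d: likelihood invariant
      double dlt = st_lvlT.s * R::norm_rand();
      double P11, P12 = 0.0;
      if (corr) {
        double det = sig2_theta * sig2_vt * (1.0 - rho * rho);
        P11 = sig2_vt / det;
        P12 = -rho * std::sqrt(sig2_theta * sig2_vt) / det;
      } else P11 = 1.0 / sig2_theta;
      double lr = lpr_fixef(beta[0] + dlt, beta[0], ab_beta, fix_bprec,
                            bprec_fix, sig2_bsh);
      if (shared && zi)
        lr += lpr_fixef(alpha[0] + zeta * dlt, alpha[0], ab_alpha, fix_aprec,
                        aprec_fix, sig2_ash);
      double sumt = arma::accu(theta), sumv = arma::accu(vartheta);
      lr += -0.5 * (P11 * (ndist * dlt * dlt - 2.0 * dlt * sumt)
                    - 2.0 * P12 * dlt * sumv);
      bool a = (std::log(R::unif_rand()) < lr);
      st_lvlT.tally(a);
      if (a) {
        beta[0] += dlt;
        theta -= dlt;
        if (shared) {
          if (zi) alpha[0] += zeta * dlt;
          vartheta = zeta * theta;
        }
      }
    }
    if (use_vt) { // alpha0 += d, vartheta -= d: likelihood invariant
      double dlt = st_lvlV.s * R::norm_rand();
      double P22, P12 = 0.0;
      if (corr) {
        double det = sig2_theta * sig2_vt * (1.0 - rho * rho);
        P22 = sig2_theta / det;
        P12 = -rho * std::sqrt(sig2_theta * sig2_vt) / det;
      } else P22 = 1.0 / sig2_vt;
      double lr = lpr_fixef(alpha[0] + dlt, alpha[0], ab_alpha, fix_aprec,
                            aprec_fix, sig2_ash);
      double sumt = arma::accu(theta), sumv = arma::accu(vartheta);
      lr += -0.5 * (P22 * (ndist * dlt * dlt - 2.0 * dlt * sumv)
                    - 2.0 * P12 * dlt * sumt);
      bool a = (std::log(R::unif_rand()) < lr);
      st_lvlV.tally(a);
      if (a) {
        alpha[0] += dlt;
        vartheta -= dlt;
      }
    }

    // ---- NB order parameter ----
    if (nbfam) {
      double lcur = std::log(r);
      double lprop = lcur + st_logr.s * R::norm_rand();
      double rprop = std::exp(lprop);
      // Gamma(a, b) prior on r, log-scale RW (Jacobian r)
      double lr = (ab_r[0]) * (lprop - lcur) - ab_r[1] * (rprop - r);
      if (!prior_only) {
        for (int k = 0; k < n; k++)
          lr += obs_ll(y[k], etaZ[k], etaC[k], family, rprop) - llv[k];
      }
      bool a = (std::log(R::unif_rand()) < lr);
      st_logr.tally(a);
      if (a) {
        r = rprop;
        refresh_ll();
      }
    }

    // ---- adaptation ----
    if (it < burnin && (it + 1) % 50 == 0) {
      for (auto& s : st_beta) s.adapt();
      for (auto& s : st_alpha) s.adapt();
      for (auto& s : st_theta) s.adapt();
      for (auto& s : st_vt) s.adapt();
      for (auto& s : st_u1) s.adapt();
      for (auto& s : st_u2) s.adapt();
      st_zeta.adapt(); st_psi.adapt(); st_logr.adapt();
      st_swapC.adapt(); st_swapZ.adapt(); st_lvlT.adapt(); st_lvlV.adapt();
    }

    // ---- store ----
    if (it >= burnin && (it - burnin) % thin == 0) {
      S_beta.row(keep) = beta.t();
      if (zi) S_alpha.row(keep) = alpha.t();
      if (use_theta) S_theta.row(keep) = theta.t();
      if (use_vt || shared) S_vt.row(keep) = vartheta.t();
      if (spatial == 3) S_u1.row(keep) = u1.t();
      if (spatial != 0) S_u2.row(keep) = u2.t();
      double dev = prior_only ? NA_REAL : -2.0 * arma::accu(llv);
      S_scal(keep, 0) = use_theta ? sig2_theta : NA_REAL;
      S_scal(keep, 1) = (use_vt || shared) ? sig2_vt : NA_REAL;
      S_scal(keep, 2) = corr ? rho : NA_REAL;
      S_scal(keep, 3) = shared ? zeta : NA_REAL;
      S_scal(keep, 4) = (spatial == 3) ? Sig_u(0, 0) : NA_REAL;
      S_scal(keep, 5) = (spatial == 3) ? Sig_u(1, 1)
                         : (spatial != 0 ? sig2_u : NA_REAL);
      S_scal(keep, 6) = (spatial == 3) ? Sig_u(0, 1) : NA_REAL;
      S_scal(keep, 7) = (spatial == 2) ? psi : NA_REAL;
      S_scal(keep, 8) = nbfam ? 1.0 / r : NA_REAL;
      S_scal(keep, 9) = dev;
      keep++;
    }
  }

  return List::create(
    _["beta"] = S_beta, _["alpha"] = S_alpha,
    _["theta"] = S_theta, _["vartheta"] = S_vt,
    _["u1"] = S_u1, _["u2"] = S_u2,
    _["scalars"] = S_scal);
}

// Posterior predictive ordinates: average over draws of the model pmf at
// each support point s = 0..smax, per observation. pi/nu are J x n matrices
// of per-draw zero-inflation probabilities and count means; rvec the
// per-draw NB size (ignored for Poisson families).
// [[Rcpp::export(name = ".ppo_cpp")]]
arma::mat ppo_cpp(const arma::mat& pi, const arma::mat& nu,
                  const arma::vec& rvec, bool nbfam, int smax) {
  const int J = nu.n_rows, n = nu.n_cols, S = smax + 1;
  arma::mat out(n, S, arma::fill::zeros);
  std::vector<double> logs(S);
  for (int s = 1; s < S; s++) logs[s] = std::log((double)s);
  for (int j = 0; j < J; j++) {
    double r = nbfam ? rvec[j] : 0.0;
    for (int k = 0; k < n; k++) {
      double nv = nu(j, k), p = pi(j, k);
      double lnv = std::log(nv);
      double lp;
      if (!nbfam) {
        lp = -nv;                         // log Poisson pmf at 0
      } else {
        lp = r * std::log(r / (r + nv));  // log NB pmf at 0
      }
      out(k, 0) += p + (1.0 - p) * std::exp(lp);
      for (int s = 1; s < S; s++) {
        if (!nbfam) {
          lp += lnv - logs[s];
        } else {
          lp += std::log(s - 1.0 + r) - logs[s] + lnv - std::log(r + nv);
        }
        out(k, s) += (1.0 - p) * std::exp(lp);
      }
    }
  }
  return out / (double)J;
}
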