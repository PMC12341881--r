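// Single-site Gibbs samplers for Bayesian variable-selection GWAS.
//
// Univariate BayesB / BayesCpi: per-SNP inclusion indicators sampled from
// their full conditional with the effect integrated out analytically, then
// the effect from its normal full conditional; locus variances (BayesB) or
// a common effect variance (BayesC) from scaled inverse chi-square; fixed
// effects with flat priors; iid random terms (pen, litter) with their own
// scaled-inv-chi-square variances; pi from its Beta full conditional when
// estimated. Window variances of genomic values are accumulated inside the
// chain for retained iterations.
//
// Bivariate BayesB: the four (delta1, delta2) combinations are sampled per
// SNP with effects marginalised under the locus covariance G_n; G_n and the
// random-term / residual covariances are refreshed from inverse Wishart
// full conditionals. Per-window covariances of the two genomic-value
// vectors across pigs are accumulated for retained iterations.
//
// All randomness flows through R's RNG so chains are bit-reproducible
// under set.seed() in single-threaded execution.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rscinv_chisq(double df, double scale_sum) {
  // draw from scaled-inv-chi^2 given df and the numerator nu*S + SS
  return scale_sum / R::rchisq(df);
}

// sample one iid random term; returns sum of squared level effects
static double update_iid_term(const IntegerVector& grp, int nlev,
                              NumericVector& a, NumericVector& e,
                              double sigma2, double sigma2_e) {
  int n = e.size();
  std::vector<double> rhs(nlev, 0.0);
  std::vector<int> cnt(nlev, 0);
  for (int i = 0; i < n; ++i) {
    e[i] += a[grp[i]];
    rhs[grp[i]] += e[i];
    cnt[grp[i]] += 1;
  }
  double lambda = sigma2_e / sigma2;
  double ss = 0.0;
  for (int l = 0; l < nlev; ++l) {
    double prec = cnt[l] + lambda;
    double mu = rhs[l] / prec;
    a[l] = mu + R::norm_rand() * std::sqrt(sigma2_e / prec);
    ss += a[l] * a[l];
  }
  for (int i = 0; i < n; ++i) e[i] -= a[grp[i]];
  return ss;
}

// [[Rcpp::export(name = ".bayesb_chain_cpp")]]
List bayesb_chain_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                      List random_groups, IntegerVector random_nlev,
                      IntegerVector window_of_snp, int n_windows,
                      double pi0, bool estimate_pi, bool common_variance,
                      int niter, int burnin, int thin,
                      double nu_beta, double s_beta,
                      double nu_e, double s_e,
                      double nu_r, double s_r,
                      bool update_locus_var, bool update_sigma_e,
                      double sigma2_e_init, int store_effects_every) {
  int n = y.size(), p = M.ncol(), nf = X.ncol();
  int nrand = random_groups.size();

  NumericVector b(nf), beta(p), sigma2_snp(p);
  LogicalVector delta(p);
  NumericVector xtx(nf), mtm(p);
  for (int j = 0; j < nf; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int k = 0; k < p; ++k) {
    double s = 0; for (int i = 0; i < n; ++i) s += M(i, k) * M(i, k);
    mtm[k] = s;
  }
  std::vector<NumericVector> rand_eff;
  NumericVector rand_var(nrand);
  for (int r = 0; r < nrand; ++r) {
    rand_eff.push_back(NumericVector(random_nlev[r]));
    rand_var[r] = s_r;
  }
  double sigma2_e = sigma2_e_init;
  double sigma2_b = s_beta * nu_beta / std::max(nu_beta - 2.0, 0.5); // BayesC common
  double pi_cur = pi0;
  for (int k = 0; k < p; ++k) sigma2_snp[k] = s_beta * nu_beta / std::max(nu_beta - 2.0, 0.5);

  NumericVector e = clone(y);
  // start residual at y - Xb with b = 0, effects 0

  int nkeep = 0;
  for (int it = burnin; it < niter; ++it) if ((it - burnin) % thin == 0) ++nkeep;

  NumericMatrix var_w(nkeep, n_windows);
  NumericMatrix rand_var_keep(nkeep, nrand > 0 ? nrand : 1);
  NumericVector var_g(nkeep), sig_e_keep(nkeep), pi_keep(nkeep);
  NumericVector pip(p), beta_mean(p);
  int n_eff_keep = (store_effects_every > 0)
    ? (nkeep + store_effects_every - 1) / store_effects_every : 0;
  NumericMatrix beta_keep(n_eff_keep > 0 ? n_eff_keep : 1,
                          n_eff_keep > 0 ? p : 1);
  IntegerMatrix delta_keep(n_eff_keep > 0 ? n_eff_keep : 1,
                           n_eff_keep > 0 ? p : 1);

  std::vector<double> gval(n), wbuf((size_t)n_windows * n);
  int keep_i = 0, eff_i = 0;
  double phen_var = var(y);
  const double* Mp = REAL(M);
  const double* Xp = REAL(X);
  double* ep = REAL(e);

  for (int it = 0; it < niter; ++it) {
    // fixed effects, flat priors
    for (int j = 0; j < nf; ++j) {
      if (xtx[j] <= 0) continue;
      const double* xj = Xp + (size_t)j * n;
      double rhs = 0;
      for (int i = 0; i < n; ++i) { ep[i] += xj[i] * b[j]; rhs += xj[i] * ep[i]; }
      double mu = rhs / xtx[j];
      b[j] = mu + R::norm_rand() * std::sqrt(sigma2_e / xtx[j]);
      for (int i = 0; i < n; ++i) ep[i] -= xj[i] * b[j];
    }
    // iid random terms and their variances (scaled-inv-chi^2, nu = 4)
    for (int r = 0; r < nrand; ++r) {
      IntegerVector grp = random_groups[r];
      double ss = update_iid_term(grp, random_nlev[r], rand_eff[r], e,
                                  rand_var[r], sigma2_e);
      rand_var[r] = rscinv_chisq(nu_r + random_nlev[r], nu_r * s_r + ss);
    }
    // SNP effects: marginalised indicator, then effect, then locus variance
    int n_in = 0;
    double log_pi = std::log(pi_cur), log_1mpi = std::log(1.0 - pi_cur);
    double ss_beta = 0.0;
    for (int k = 0; k < p; ++k) {
      double c = mtm[k];
      if (c <= 0) { delta[k] = false; beta[k] = 0; continue; }
      const double* mk = Mp + (size_t)k * n;
      double alpha_old = delta[k] ? beta[k] : 0.0;
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += mk[i] * ep[i];
      rhs += c * alpha_old;
      double s2 = common_variance ? sigma2_b : sigma2_snp[k];
      double v0 = c * sigma2_e;
      double v1 = c * c * s2 + v0;
      double log_f0 = -0.5 * std::log(v0) - 0.5 * rhs * rhs / v0;
      double log_f1 = -0.5 * std::log(v1) - 0.5 * rhs * rhs / v1;
      double lodds = log_1mpi + log_f1 - (log_pi + log_f0);
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      bool inc = unif_rand() < p1;
      double alpha_new = 0.0;
      if (inc) {
        double prec = c + sigma2_e / s2;
        double mu = rhs / prec;
        alpha_new = mu + R::norm_rand() * std::sqrt(sigma2_e / prec);
        beta[k] = alpha_new;
        ++n_in;
        ss_beta += alpha_new * alpha_new;
      } else {
        beta[k] = 0.0;
      }
      delta[k] = inc;
      if (alpha_new != alpha_old) {
        double d = alpha_old - alpha_new;
        for (int i = 0; i < n; ++i) ep[i] += mk[i] * d;
      }
      if (update_locus_var && !common_variance) {
        if (inc)
          sigma2_snp[k] = rscinv_chisq(nu_beta + 1.0,
                                       nu_beta * s_beta + beta[k] * beta[k]);
        else
          sigma2_snp[k] = rscinv_chisq(nu_beta, nu_beta * s_beta);
      }
    }
    if (update_locus_var && common_variance) {
      sigma2_b = rscinv_chisq(nu_beta + n_in, nu_beta * s_beta + ss_beta);
    }
    if (estimate_pi) {
      pi_cur = R::rbeta(p - n_in + 1.0, n_in + 1.0);
      if (pi_cur <= 1e-12) pi_cur = 1e-12;
      if (pi_cur >= 1.0 - 1e-12) pi_cur = 1.0 - 1e-12;
    }
    // residual variance
    if (update_sigma_e) {
      double sse = 0; for (int i = 0; i < n; ++i) sse += ep[i] * ep[i];
      sigma2_e = rscinv_chisq(nu_e + n, nu_e * s_e + sse);
    }
    if (sigma2_e > 1e6 * phen_var) {
      stop("divergence guard: residual variance exceeded 1e6 x phenotypic variance at iteration %d", it + 1);
    }
    // record retained iterations
    if (it >= burnin && (it - burnin) % thin == 0) {
      std::fill(gval.begin(), gval.end(), 0.0);
      std::fill(wbuf.begin(), wbuf.end(), 0.0);
      for (int k = 0; k < p; ++k) {
        if (!delta[k]) continue;
        double bk = beta[k];
        const double* mk = Mp + (size_t)k * n;
        double* col = &wbuf[(size_t)window_of_snp[k] * n];
        for (int i = 0; i < n; ++i) col[i] += mk[i] * bk;
      }
      for (int w = 0; w < n_windows; ++w) {
        double* col = &wbuf[(size_t)w * n];
        double mean = 0, ss = 0;
        for (int i = 0; i < n; ++i) { mean += col[i]; gval[i] += col[i]; }
        mean /= n;
        for (int i = 0; i < n; ++i) { double d = col[i] - mean; ss += d * d; }
        var_w(keep_i, w) = (n > 1) ? ss / (n - 1) : 0.0;
      }
      double gm = 0, gss = 0;
      for (int i = 0; i < n; ++i) gm += gval[i];
      gm /= n;
      for (int i = 0; i < n; ++i) { double d = gval[i] - gm; gss += d * d; }
      var_g[keep_i] = (n > 1) ? gss / (n - 1) : 0.0;
      sig_e_keep[keep_i] = sigma2_e;
      pi_keep[keep_i] = pi_cur;
      for (int r = 0; r < nrand; ++r) rand_var_keep(keep_i, r) = rand_var[r];
      for (int k = 0; k < p; ++k) {
        if (delta[k]) { pip[k] += 1.0; beta_mean[k] += beta[k]; }
      }
      if (store_effects_every > 0 && keep_i % store_effects_every == 0) {
        for (int k = 0; k < p; ++k) {
          beta_keep(eff_i, k) = beta[k];
          delta_keep(eff_i, k) = delta[k] ? 1 : 0;
        }
        ++eff_i;
      }
      ++keep_i;
    }
  }
  for (int k = 0; k < p; ++k) {
    beta_mean[k] = (pip[k] > 0) ? beta_mean[k] / nkeep : 0.0;
    pip[k] /= nkeep;
  }
  List out = List::create(
    _["pip"] = pip, _["beta_mean"] = beta_mean,
    _["var_window"] = var_w, _["var_genomic"] = var_g,
    _["sigma2_e"] = sig_e_keep, _["pi"] = pi_keep,
    _["rand_var"] = rand_var_keep, _["n_kept"] = nkeep);
  if (store_effects_every > 0) {
    out["beta_samples"] = beta_keep;
    out["delta_samples"] = delta_keep;
  }
  return out;
}

// ---- bivariate ----------------------------------------------------------

static inline void inv2(const double A[4], double out[4]) {
  double det = A[0] * A[3] - A[1] * A[2];
  out[0] = A[3] / det; out[3] = A[0] / det;
  out[1] = -A[1] / det; out[2] = -A[2] / det;
}

// inverse Wishart draw for a 2x2 scale matrix Psi with df nu (Bartlett on
// the Wishart of Psi^{-1}, then invert)
static void riwish2(double nu, const double Psi[4], double out[4]) {
  double Pinv[4];
  inv2(Psi, Pinv);
  // Cholesky of Pinv = L L'
  double l11 = std::sqrt(Pinv[0]);
  double l21 = Pinv[2] / l11;
  double l22 = std::sqrt(std::max(Pinv[3] - l21 * l21, 1e-300));
  // Bartlett: A lower-triangular, diag chi, off-diag normal
  double a11 = std::sqrt(R::rchisq(nu));
  double a22 = std::sqrt(R::rchisq(nu - 1.0));
  double a21 = R::norm_rand();
  // T = L A ; W = T T' ~ Wishart(nu, Pinv)
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double W[4];
  W[0] = t11 * t11; W[1] = t11 * t21; W[2] = W[1];
  W[3] = t21 * t21 + t22 * t22;
  inv2(W, out);
}

// [[Rcpp::export(name = ".bayesb_bv_chain_cpp")]]
List bayesb_bv_chain_cpp(NumericMatrix Y, NumericMatrix X, NumericMatrix M,
                         List random_groups, IntegerVector random_nlev,
                         IntegerVector window_of_snp, int n_windows,
                         double pi0, int niter, int burnin, int thin,
                         double nu_beta, NumericMatrix S_beta,
                         double nu_e, NumericMatrix S_e,
                         double nu_r, NumericMatrix S_r,
                         int store_effects_every) {
  int n = Y.nrow(), p = M.ncol(), nf = X.ncol();
  int nrand = random_groups.size();

  NumericMatrix b(nf, 2), beta(p, 2);
  IntegerMatrix delta(p, 2);
  std::vector<double> Gn(4 * p);
  double G0[4] = { S_beta(0, 0) * nu_beta / std::max(nu_beta - 3.0, 0.5), 0.0,
                   0.0, S_beta(1, 1) * nu_beta / std::max(nu_beta - 3.0, 0.5) };
  for (int k = 0; k < p; ++k) {
    Gn[4 * k] = G0[0]; Gn[4 * k + 1] = 0; Gn[4 * k + 2] = 0; Gn[4 * k + 3] = G0[3];
  }
  NumericVector xtx(nf), mtm(p);
  for (int j = 0; j < nf; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int k = 0; k < p; ++k) {
    double s = 0; for (int i = 0; i < n; ++i) s += M(i, k) * M(i, k);
    mtm[k] = s;
  }
  std::vector<NumericMatrix> rand_eff;
  std::vector<std::array<double, 4>> rand_cov(nrand);
  for (int r = 0; r < nrand; ++r) {
    rand_eff.push_back(NumericMatrix(random_nlev[r], 2));
    rand_cov[r] = { S_r(0, 0), 0.0, 0.0, S_r(1, 1) };
  }
  double Rcov[4] = { S_e(0, 0), 0.0, 0.0, S_e(1, 1) };

  NumericMatrix E(n, 2);
  for (int i = 0; i < n; ++i) { E(i, 0) = Y(i, 0); E(i, 1) = Y(i, 1); }

  // prior over the 4 indicator combinations [00, 01, 10, 11]
  double prior[4] = { pi0 * pi0, pi0 * (1 - pi0), (1 - pi0) * pi0,
                      (1 - pi0) * (1 - pi0) };
  double logprior[4];
  for (int s = 0; s < 4; ++s) logprior[s] = std::log(prior[s]);

  int nkeep = 0;
  for (int it = burnin; it < niter; ++it) if ((it - burnin) % thin == 0) ++nkeep;
  NumericMatrix cov_w(nkeep, n_windows);
  NumericMatrix var_w1(nkeep, n_windows), var_w2(nkeep, n_windows);
  NumericVector cov_g(nkeep);
  NumericMatrix pip(p, 2);
  NumericVector pip_both(p);
  int n_eff_keep = (store_effects_every > 0)
    ? (nkeep + store_effects_every - 1) / store_effects_every : 0;
  NumericMatrix beta1_keep(n_eff_keep > 0 ? n_eff_keep : 1,
                           n_eff_keep > 0 ? p : 1);
  NumericMatrix beta2_keep(n_eff_keep > 0 ? n_eff_keep : 1,
                           n_eff_keep > 0 ? p : 1);

  std::vector<double> g1(n), g2(n);
  std::vector<double> wbuf1((size_t)n_windows * n), wbuf2((size_t)n_windows * n);
  const double* Mbv = REAL(M);
  double* E1p = REAL(E);
  double* E2p = REAL(E) + n;
  int keep_i = 0, eff_i = 0;
  double phen_var = (var(Y(_, 0)) + var(Y(_, 1))) / 2.0;

  for (int it = 0; it < niter; ++it) {
    double W[4];
    inv2(Rcov, W);
    // fixed effects per trait, flat priors, correlated-residual weighting
    for (int t = 0; t < 2; ++t) {
      int o = 1 - t;
      double wtt = (t == 0) ? W[0] : W[3];
      double wto = W[1];
      for (int j = 0; j < nf; ++j) {
        if (xtx[j] <= 0) continue;
        double rhs = 0;
        for (int i = 0; i < n; ++i) {
          E(i, t) += X(i, j) * b(j, t);
          rhs += X(i, j) * (wtt * E(i, t) + wto * E(i, o));
        }
        double prec = xtx[j] * wtt;
        double mu = rhs / prec;
        b(j, t) = mu + R::norm_rand() / std::sqrt(prec);
        for (int i = 0; i < n; ++i) E(i, t) -= X(i, j) * b(j, t);
      }
    }
    // iid random terms (bivariate levels) and their covariances
    for (int r = 0; r < nrand; ++r) {
      IntegerVector grp = random_groups[r];
      int q = random_nlev[r];
      std::vector<double> rhs1(q, 0.0), rhs2(q, 0.0);
      std::vector<int> cnt(q, 0);
      NumericMatrix& a = rand_eff[r];
      for (int i = 0; i < n; ++i) {
        int l = grp[i];
        E(i, 0) += a(l, 0); E(i, 1) += a(l, 1);
        rhs1[l] += W[0] * E(i, 0) + W[1] * E(i, 1);
        rhs2[l] += W[1] * E(i, 0) + W[3] * E(i, 1);
        cnt[l] += 1;
      }
      double Uinv[4];
      inv2(rand_cov[r].data(), Uinv);
      double SSa[4] = { 0, 0, 0, 0 };
      for (int l = 0; l < q; ++l) {
        double A[4] = { cnt[l] * W[0] + Uinv[0], cnt[l] * W[1] + Uinv[1],
                        cnt[l] * W[1] + Uinv[2], cnt[l] * W[3] + Uinv[3] };
        double Ainv[4];
        inv2(A, Ainv);
        double m1 = Ainv[0] * rhs1[l] + Ainv[1] * rhs2[l];
        double m2 = Ainv[2] * rhs1[l] + Ainv[3] * rhs2[l];
        // draw from N(m, Ainv) via Cholesky of Ainv
        double l11 = std::sqrt(Ainv[0]);
        double l21 = Ainv[2] / l11;
        double l22 = std::sqrt(std::max(Ainv[3] - l21 * l21, 1e-300));
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        a(l, 0) = m1 + l11 * z1;
        a(l, 1) = m2 + l21 * z1 + l22 * z2;
        SSa[0] += a(l, 0) * a(l, 0); SSa[1] += a(l, 0) * a(l, 1);
        SSa[3] += a(l, 1) * a(l, 1);
      }
      SSa[2] = SSa[1];
      for (int i = 0; i < n; ++i) {
        int l = grp[i];
        E(i, 0) -= a(l, 0); E(i, 1) -= a(l, 1);
      }
      double Psi[4] = { S_r(0, 0) + SSa[0], S_r(0, 1) + SSa[1],
                        S_r(1, 0) + SSa[2], S_r(1, 1) + SSa[3] };
      riwish2(nu_r + q, Psi, rand_cov[r].data());
    }
    inv2(Rcov, W);
    // SNP effects: sample one of the 4 indicator combinations, marginalised
    for (int k = 0; k < p; ++k) {
      double c = mtm[k];
      if (c <= 0) continue;
      const double* mk = Mbv + (size_t)k * n;
      double a1 = delta(k, 0) ? beta(k, 0) : 0.0;
      double a2 = delta(k, 1) ? beta(k, 1) : 0.0;
      double r1 = 0, r2 = 0;
      for (int i = 0; i < n; ++i) {
        double m = mk[i];
        double e1 = E1p[i] + m * a1;
        double e2 = E2p[i] + m * a2;
        r1 += m * (W[0] * e1 + W[1] * e2);
        r2 += m * (W[1] * e1 + W[3] * e2);
      }
      double* G = &Gn[4 * k];
      double logw[4];
      logw[0] = logprior[0];
      // single-trait combos
      {
        // trait 1 only: precision cW11 + 1/G11
        double A = c * W[0] + 1.0 / G[0];
        logw[2] = logprior[2] - 0.5 * std::log(G[0] * A) + 0.5 * r1 * r1 / A;
        double B = c * W[3] + 1.0 / G[3];
        logw[1] = logprior[1] - 0.5 * std::log(G[3] * B) + 0.5 * r2 * r2 / B;
      }
      {
        double Ginv[4];
        inv2(G, Ginv);
        double A[4] = { c * W[0] + Ginv[0], c * W[1] + Ginv[1],
                        c * W[1] + Ginv[2], c * W[3] + Ginv[3] };
        double detA = A[0] * A[3] - A[1] * A[2];
        double detG = G[0] * G[3] - G[1] * G[2];
        double Ainv[4];
        inv2(A, Ainv);
        double quad = r1 * (Ainv[0] * r1 + Ainv[1] * r2) +
                      r2 * (Ainv[2] * r1 + Ainv[3] * r2);
        logw[3] = logprior[3] - 0.5 * std::log(detG * detA) + 0.5 * quad;
      }
      double mx = std::max(std::max(logw[0], logw[1]),
                           std::max(logw[2], logw[3]));
      double wsum = 0, wprob[4];
      for (int s = 0; s < 4; ++s) { wprob[s] = std::exp(logw[s] - mx); wsum += wprob[s]; }
      double u = unif_rand() * wsum;
      int combo = 0;
      for (int s = 0; s < 4; ++s) { u -= wprob[s]; if (u <= 0) { combo = s; break; } }
      double b1 = 0, b2 = 0;
      if (combo == 2) {            // trait 1 only
        double A = c * W[0] + 1.0 / G[0];
        b1 = r1 / A + R::norm_rand() / std::sqrt(A);
      } else if (combo == 1) {     // trait 2 only
        double B = c * W[3] + 1.0 / G[3];
        b2 = r2 / B + R::norm_rand() / std::sqrt(B);
      } else if (combo == 3) {
        double Ginv[4];
        inv2(G, Ginv);
        double A[4] = { c * W[0] + Ginv[0], c * W[1] + Ginv[1],
                        c * W[1] + Ginv[2], c * W[3] + Ginv[3] };
        double Ainv[4];
        inv2(A, Ainv);
        double m1 = Ainv[0] * r1 + Ainv[1] * r2;
        double m2 = Ainv[2] * r1 + Ainv[3] * r2;
        double l11 = std::sqrt(Ainv[0]);
        double l21 = Ainv[2] / l11;
        double l22 = std::sqrt(std::max(Ainv[3] - l21 * l21, 1e-300));
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        b1 = m1 + l11 * z1;
        b2 = m2 + l21 * z1 + l22 * z2;
      }
      delta(k, 0) = (combo == 2 || combo == 3) ? 1 : 0;
      delta(k, 1) = (combo == 1 || combo == 3) ? 1 : 0;
      beta(k, 0) = b1; beta(k, 1) = b2;
      if (b1 != a1 || b2 != a2) {
        double d1 = a1 - b1, d2 = a2 - b2;
        for (int i = 0; i < n; ++i) {
          E1p[i] += mk[i] * d1;
          E2p[i] += mk[i] * d2;
        }
      }
      // locus covariance from its inverse Wishart full conditional
      double Psi[4] = { S_beta(0, 0) + b1 * b1, S_beta(0, 1) + b1 * b2,
                        S_beta(1, 0) + b1 * b2, S_beta(1, 1) + b2 * b2 };
      riwish2(nu_beta + 1.0, Psi, G);
    }
    // residual covariance
    double SSe[4] = { 0, 0, 0, 0 };
    for (int i = 0; i < n; ++i) {
      SSe[0] += E(i, 0) * E(i, 0);
      SSe[1] += E(i, 0) * E(i, 1);
      SSe[3] += E(i, 1) * E(i, 1);
    }
    SSe[2] = SSe[1];
    double Psi_e[4] = { S_e(0, 0) + SSe[0], S_e(0, 1) + SSe[1],
                        S_e(1, 0) + SSe[2], S_e(1, 1) + SSe[3] };
    riwish2(nu_e + n, Psi_e, Rcov);
    if (Rcov[0] > 1e6 * phen_var || Rcov[3] > 1e6 * phen_var) {
      stop("divergence guard: residual variance exceeded 1e6 x phenotypic variance at iteration %d", it + 1);
    }
    // record
    if (it >= burnin && (it - burnin) % thin == 0) {
      std::fill(g1.begin(), g1.end(), 0.0);
      std::fill(g2.begin(), g2.end(), 0.0);
      std::fill(wbuf1.begin(), wbuf1.end(), 0.0);
      std::fill(wbuf2.begin(), wbuf2.end(), 0.0);
      for (int k = 0; k < p; ++k) {
        size_t off = (size_t)window_of_snp[k] * n;
        const double* mk = Mbv + (size_t)k * n;
        if (delta(k, 0)) {
          double bk = beta(k, 0);
          for (int i = 0; i < n; ++i) wbuf1[off + i] += mk[i] * bk;
        }
        if (delta(k, 1)) {
          double bk = beta(k, 1);
          for (int i = 0; i < n; ++i) wbuf2[off + i] += mk[i] * bk;
        }
      }
      for (int w = 0; w < n_windows; ++w) {
        double* c1 = &wbuf1[(size_t)w * n];
        double* c2 = &wbuf2[(size_t)w * n];
        double m1 = 0, m2 = 0, cv = 0, v1 = 0, v2 = 0;
        for (int i = 0; i < n; ++i) {
          m1 += c1[i]; m2 += c2[i]; g1[i] += c1[i]; g2[i] += c2[i];
        }
        m1 /= n; m2 /= n;
        for (int i = 0; i < n; ++i) {
          double d1 = c1[i] - m1, d2 = c2[i] - m2;
          cv += d1 * d2; v1 += d1 * d1; v2 += d2 * d2;
        }
        cov_w(keep_i, w) = cv / (n - 1);
        var_w1(keep_i, w) = v1 / (n - 1);
        var_w2(keep_i, w) = v2 / (n - 1);
      }
      double m1 = 0, m2 = 0, cg = 0;
      for (int i = 0; i < n; ++i) { m1 += g1[i]; m2 += g2[i]; }
      m1 /= n; m2 /= n;
      for (int i = 0; i < n; ++i) cg += (g1[i] - m1) * (g2[i] - m2);
      cov_g[keep_i] = cg / (n - 1);
      for (int k = 0; k < p; ++k) {
        if (delta(k, 0)) pip(k, 0) += 1.0;
        if (delta(k, 1)) pip(k, 1) += 1.0;
        if (delta(k, 0) && delta(k, 1)) pip_both[k] += 1.0;
      }
      if (store_effects_every > 0 && keep_i % store_effects_every == 0) {
        for (int k = 0; k < p; ++k) {
          beta1_keep(eff_i, k) = delta(k, 0) ? beta(k, 0) : 0.0;
          beta2_keep(eff_i, k) = delta(k, 1) ? beta(k, 1) : 0.0;
        }
        ++eff_i;
      }
      ++keep_i;
    }
  }
  for (int k = 0; k < p; ++k) {
    pip(k, 0) /= nkeep; pip(k, 1) /= nkeep; pip_both[k] /= nkeep;
  }
  List out = List::create(
    _["pip"] = pip, _["pip_both"] = pip_both,
    _["cov_window"] = cov_w, _["var_window1"] = var_w1,
    _["var_window2"] = var_w2, _["cov_genomic"] = cov_g,
    _["n_kept"] = nkeep);
  if (store_effects_every > 0) {
    out["beta1_samples"] = beta1_keep;
    out["beta2_samples"] = beta2_keep;
  }
  return out;
}
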