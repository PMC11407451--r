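// Gibbs sampler core for the two-layer methylation -> expression -> outcome
// hierarchical model with Dirac spike-and-slab selection, an MRF network
// prior on gene-level indicators, block-missingness data augmentation and
// latent-variable handling of probit / AFT outcomes.
//
// All randomness goes through R's RNG so that set.seed() in R makes every
// run bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

// ---------------------------------------------------------------------------
// truncated normal draws: inverse-CDF in log space so extreme truncation
// points stay accurate deep into the tails
// ---------------------------------------------------------------------------

static double rtnorm_lower1(double mu, double sd, double lower) {
  double a = (lower - mu) / sd;
  double u = R::unif_rand();
  // want z with S(z) = u * S(a), S = upper-tail prob
  double logS = R::pnorm(a, 0.0, 1.0, 0, 1);
  double z = R::qnorm(std::log(u) + logS, 0.0, 1.0, 0, 1);
  return mu + sd * z;
}

static double rtnorm_upper1(double mu, double sd, double upper) {
  return -rtnorm_lower1(-mu, sd, -upper);
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm_lower(int n, double mu, double sd, double lower) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_lower1(mu, sd, lower);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm_upper(int n, double mu, double sd, double upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_upper1(mu, sd, upper);
  return out;
}

// ---------------------------------------------------------------------------
// small-matrix helpers
// ---------------------------------------------------------------------------

// log marginal likelihood (up to configuration-independent constants) of the
// active-set ridge-type Gaussian model:
//   A = c1 * G_SS + lam * I,  h = h_S,  logm = q/2 log(lam) - 1/2 log|A| +
//   1/2 h' A^{-1} h
static double log_marg_active(const mat& G, const vec& h, const uvec& S,
                              double c1, double lam) {
  int q = S.n_elem;
  if (q == 0) return 0.0;
  mat A = c1 * G.submat(S, S);
  A.diag() += lam;
  mat L = arma::chol(A, "lower");
  vec hs = h.elem(S);
  vec w = arma::solve(arma::trimatl(L), hs);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return 0.5 * q * std::log(lam) - 0.5 * logdet + 0.5 * arma::dot(w, w);
}

// draw omega_S ~ N(A^{-1} h_S, A^{-1})
static vec draw_gaussian_active(const mat& G, const vec& h, const uvec& S,
                                double c1, double lam) {
  int q = S.n_elem;
  mat A = c1 * G.submat(S, S);
  A.diag() += lam;
  mat L = arma::chol(A, "lower");
  vec hs = h.elem(S);
  vec m = arma::solve(arma::trimatu(L.t()),
                      arma::solve(arma::trimatl(L), hs));
  vec z(q);
  for (int i = 0; i < q; ++i) z[i] = R::norm_rand();
  return m + arma::solve(arma::trimatu(L.t()), z);
}

// ---------------------------------------------------------------------------
// mechanistic block: single-site Gibbs on z_{jk} with omega integrated out,
// then a conjugate multivariate-normal redraw of the active omega_{.k}.
// When `couple` is true the clinical likelihood enters through
//   Rk ~ N(bk * Mk omega_k, sigma2 I),  bk = betaM_k - betaMbar_k.
// ---------------------------------------------------------------------------

static void mech_gene_core(const mat& Mk, const vec& Ek, const vec& Rk,
                           arma::ivec& zk, vec& omk,
                           double& sig2k, double& pik,
                           double bk, double sigma2, bool couple,
                           double tau_k, double a, double b,
                           double d1, double d2,
                           bool update_pi, bool update_var) {
  int p = Mk.n_cols;
  int N = Mk.n_rows;
  mat G = Mk.t() * Mk;
  vec hE = Mk.t() * Ek;
  vec hR = couple ? vec(Mk.t() * Rk) : vec(p, arma::fill::zeros);

  double c_eff = couple ? (bk * bk) : 0.0;
  double c1 = 1.0 / sig2k + c_eff / sigma2;
  double lam = tau_k / sig2k;
  vec h = hE / sig2k;
  if (couple && bk != 0.0) h += (bk / sigma2) * hR;

  double lpi = std::log(pik), lqi = std::log1p(-pik);
  for (int j = 0; j < p; ++j) {
    // active sets with and without j
    std::vector<arma::uword> s0, s1;
    for (int l = 0; l < p; ++l) {
      if (l == j) continue;
      if (zk[l] == 1) { s0.push_back(l); s1.push_back(l); }
    }
    s1.push_back(j);
    uvec S0(s0), S1(s1);
    double lm0 = log_marg_active(G, h, S0, c1, lam) +
                 (int)S0.n_elem * lpi + (p - (int)S0.n_elem) * lqi;
    double lm1 = log_marg_active(G, h, S1, c1, lam) +
                 (int)S1.n_elem * lpi + (p - (int)S1.n_elem) * lqi;
    double pr1 = 1.0 / (1.0 + std::exp(lm0 - lm1));
    zk[j] = (R::unif_rand() < pr1) ? 1 : 0;
  }

  // redraw omega: inactive entries exactly zero (Dirac spike)
  omk.zeros();
  uvec S = arma::find(arma::conv_to<uvec>::from(zk) == 1);
  if (S.n_elem > 0) {
    vec om = draw_gaussian_active(G, h, S, c1, lam);
    omk.elem(S) = om;
  }
  int q = S.n_elem;

  if (update_pi) pik = R::rbeta(a + q, b + p - q);

  if (update_var) {
    vec res = Ek - Mk * omk;
    double rate = d2 + 0.5 * arma::dot(res, res) +
                  0.5 * tau_k * arma::dot(omk, omk);
    sig2k = 1.0 / R::rgamma(d1 + 0.5 * (N + q), 1.0 / rate);
  }
}

// Exposed wrapper so tests can exercise exactly the code path the full
// sampler uses, one gene at a time.
// [[Rcpp::export]]
List cpp_mech_gene_update(const arma::mat& Mk, const arma::vec& Ek,
                          const arma::vec& Rk,
                          arma::ivec zk, arma::vec omk,
                          double sig2k, double pik,
                          double bk, double sigma2, bool couple,
                          double tau_k, double a, double b,
                          double d1, double d2,
                          bool update_pi, bool update_var) {
  mech_gene_core(Mk, Ek, Rk, zk, omk, sig2k, pik, bk, sigma2, couple,
                 tau_k, a, b, d1, d2, update_pi, update_var);
  return List::create(_["z"] = zk, _["omega"] = omk,
                      _["sigma2_k"] = sig2k, _["pi_k"] = pik);
}

// ---------------------------------------------------------------------------
// clinical block: joint enumeration of the four (gammaM, gammaMbar)
// configurations for one gene with the active betas integrated out
// analytically; the MRF prior acts on gamma = gammaM OR gammaMbar, and the
// three active configurations share it according to `log_alloc`.
// ---------------------------------------------------------------------------

static void clin_gene_core(const vec& xM, const vec& xB, const vec& s,
                           double prior_logit, const vec& log_alloc,
                           double tau, double sigma2,
                           int& gM, int& gB, double& bM, double& bB) {
  double gMM = arma::dot(xM, xM), gBB = arma::dot(xB, xB),
         gMB = arma::dot(xM, xB);
  double hM = arma::dot(xM, s), hB = arma::dot(xB, s);

  // log marginal (relative to the empty configuration) for each config
  auto lm1 = [&](double gxx, double hx) {
    double A = gxx + tau;
    return 0.5 * std::log(tau) - 0.5 * std::log(A) +
           hx * hx / (2.0 * sigma2 * A);
  };
  double l00 = 0.0;
  double l10 = lm1(gMM, hM);  // gammaM only
  double l01 = lm1(gBB, hB);  // gammaMbar only
  double l11;
  {
    mat A(2, 2);
    A(0, 0) = gMM + tau; A(1, 1) = gBB + tau; A(0, 1) = A(1, 0) = gMB;
    double det = A(0, 0) * A(1, 1) - gMB * gMB;
    // A^{-1} h quadratic form
    double quad = (A(1, 1) * hM * hM - 2.0 * gMB * hM * hB +
                   A(0, 0) * hB * hB) / det;
    l11 = std::log(tau) - 0.5 * std::log(det) + quad / (2.0 * sigma2);
  }

  double w[4];
  w[0] = l00;
  w[1] = l10 + prior_logit + log_alloc[0];
  w[2] = l01 + prior_logit + log_alloc[1];
  w[3] = l11 + prior_logit + log_alloc[2];
  double mx = std::max(std::max(w[0], w[1]), std::max(w[2], w[3]));
  double tot = 0.0;
  for (int i = 0; i < 4; ++i) { w[i] = std::exp(w[i] - mx); tot += w[i]; }
  double u = R::unif_rand() * tot, cum = 0.0;
  int cfg = 3;
  for (int i = 0; i < 4; ++i) { cum += w[i]; if (u <= cum) { cfg = i; break; } }

  gM = (cfg == 1 || cfg == 3) ? 1 : 0;
  gB = (cfg == 2 || cfg == 3) ? 1 : 0;
  bM = 0.0; bB = 0.0;
  double sd = std::sqrt(sigma2);
  if (cfg == 1) {
    double A = gMM + tau;
    bM = hM / A + sd / std::sqrt(A) * R::norm_rand();
  } else if (cfg == 2) {
    double A = gBB + tau;
    bB = hB / A + sd / std::sqrt(A) * R::norm_rand();
  } else if (cfg == 3) {
    mat A(2, 2);
    A(0, 0) = gMM + tau; A(1, 1) = gBB + tau; A(0, 1) = A(1, 0) = gMB;
    mat L = arma::chol(A, "lower");
    vec h = {hM, hB};
    vec m = arma::solve(arma::trimatu(L.t()),
                        arma::solve(arma::trimatl(L), h));
    vec z = {R::norm_rand(), R::norm_rand()};
    vec bb = m + sd * arma::solve(arma::trimatu(L.t()), z);
    bM = bb[0]; bB = bb[1];
  }
}

// [[Rcpp::export]]
List cpp_clin_gene_update(const arma::vec& xM, const arma::vec& xB,
                          const arma::vec& s, double prior_logit,
                          const arma::vec& log_alloc,
                          double tau, double sigma2) {
  int gM, gB; double bM, bB;
  clin_gene_core(xM, xB, s, prior_logit, log_alloc, tau, sigma2,
                 gM, gB, bM, bB);
  return List::create(_["gamma_M"] = gM, _["gamma_Mbar"] = gB,
                      _["beta_M"] = bM, _["beta_Mbar"] = bB);
}

// ---------------------------------------------------------------------------
// imputation conditionals (single cell); the same functions drive the main
// loop and the exported moment/draw helpers used by the tests
// ---------------------------------------------------------------------------

// missing expression cell e_{nk}: mechanistic mean m_mech with variance
// sig2k, plus (optionally) the clinical observation with coefficient bMbar
// and partial residual rho ~ N(e * bMbar, sigma2)
static void impute_e_moments(double m_mech, double sig2k, double bMbar,
                             double rho, double sigma2, bool modular,
                             double& mean, double& var) {
  double prec = 1.0 / sig2k, num = m_mech / sig2k;
  if (!modular && bMbar != 0.0) {
    prec += bMbar * bMbar / sigma2;
    num += bMbar * rho / sigma2;
  }
  var = 1.0 / prec;
  mean = num * var;
}

// missing methylation cell m_{nj}: N(0, sm2) prior, mechanistic likelihood
// through omega_j (partial residual e_part, variance sig2k), clinical
// likelihood through omega_j * bk (partial residual rho, variance sigma2)
static void impute_m_moments(double sm2, double om_j, double sig2k,
                             double e_part, double bk, double rho,
                             double sigma2, bool modular,
                             double& mean, double& var) {
  double prec = 1.0 / sm2, num = 0.0;
  if (!modular && om_j != 0.0) {
    prec += om_j * om_j / sig2k;
    num += om_j * e_part / sig2k;
    double c = om_j * bk;
    if (c != 0.0) {
      prec += c * c / sigma2;
      num += c * rho / sigma2;
    }
  }
  var = 1.0 / prec;
  mean = num * var;
}

// [[Rcpp::export]]
NumericVector cpp_impute_e_moments(double m_mech, double sig2k, double bMbar,
                                   double rho, double sigma2, bool modular) {
  double mean, var;
  impute_e_moments(m_mech, sig2k, bMbar, rho, sigma2, modular, mean, var);
  return NumericVector::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_impute_m_moments(double sm2, double om_j, double sig2k,
                                   double e_part, double bk, double rho,
                                   double sigma2, bool modular) {
  double mean, var;
  impute_m_moments(sm2, om_j, sig2k, e_part, bk, rho, sigma2, modular,
                   mean, var);
  return NumericVector::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_impute_e_draws(int n, double m_mech, double sig2k,
                                 double bMbar, double rho, double sigma2,
                                 bool modular) {
  double mean, var;
  impute_e_moments(m_mech, sig2k, bMbar, rho, sigma2, modular, mean, var);
  NumericVector out(n);
  double sd = std::sqrt(var);
  for (int i = 0; i < n; ++i) out[i] = mean + sd * R::norm_rand();
  return out;
}

// ---------------------------------------------------------------------------
// full sampler
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_netmim(const arma::mat& C, arma::mat E, arma::mat M,
                    const arma::vec& y_obs, const arma::ivec& event,
                    int outcome_type, // 0 continuous, 1 binary, 2 survival
                    const List& Jk_list, const List& nbr_list,
                    const arma::ivec& uE, const arma::ivec& uM,
                    double d, double f, double tau, const arma::vec& tau_k,
                    double tau_c, double a, double b,
                    double d1, double d2, const arma::vec& sigma_m,
                    const arma::vec& alloc,
                    int T, int Tb, int thin,
                    bool store_omega, bool modular_mech, bool modular_imp,
                    bool clin_first, bool geweke,
                    arma::ivec z, arma::vec omega,
                    arma::vec sigma2_k, arma::vec pi_k,
                    arma::ivec gamma_M, arma::ivec gamma_B,
                    arma::vec beta_M, arma::vec beta_B, arma::vec beta_C,
                    double sigma2,
                    const arma::mat& C_new, const arma::mat& E_new,
                    const arma::mat& M_new,
                    bool verbose) {
  const int N = E.n_rows, K = E.n_cols, J = M.n_cols, Lc = C.n_cols;
  const int Nv = C_new.n_rows;

  std::vector<uvec> Jk(K);
  for (int k = 0; k < K; ++k) Jk[k] = as<uvec>(Jk_list[k]);
  std::vector<uvec> nbr(K);
  for (int k = 0; k < K; ++k) nbr[k] = as<uvec>(nbr_list[k]);
  arma::ivec gene_of(J);
  for (int k = 0; k < K; ++k)
    for (arma::uword t = 0; t < Jk[k].n_elem; ++t) gene_of[Jk[k][t]] = k;

  vec log_alloc = arma::log(alloc);

  // latent outcome
  vec ystar(N);
  if (outcome_type == 0) ystar = y_obs;
  else if (outcome_type == 1) {
    for (int n = 0; n < N; ++n) ystar[n] = (y_obs[n] > 0.5) ? 0.5 : -0.5;
    sigma2 = 1.0;
  } else {
    for (int n = 0; n < N; ++n) ystar[n] = std::log(y_obs[n]);
  }

  // cache of M Omega by gene
  mat xM(N, K, arma::fill::zeros);
  auto recompute_xM_col = [&](int k) {
    xM.col(k) = M.cols(Jk[k]) * omega.elem(Jk[k]);
  };
  for (int k = 0; k < K; ++k) recompute_xM_col(k);

  auto recompute_resid = [&](vec& r) {
    vec mu = C * beta_C;
    for (int k = 0; k < K; ++k) {
      if (beta_B[k] != 0.0) mu += beta_B[k] * (E.col(k) - xM.col(k));
      if (beta_M[k] != 0.0) mu += beta_M[k] * xM.col(k);
    }
    r = ystar - mu;
  };
  vec r;
  recompute_resid(r);

  std::vector<int> misE, misM;
  for (int n = 0; n < N; ++n) {
    if (uE[n] == 1) misE.push_back(n);
    if (uM[n] == 1) misM.push_back(n);
  }

  int n_keep = 0;
  for (int t = Tb; t < T; ++t) if ((t - Tb) % thin == 0) ++n_keep;

  mat dr_gM(n_keep, K), dr_gB(n_keep, K), dr_bM(n_keep, K), dr_bB(n_keep, K);
  mat dr_z(n_keep, J), dr_bC(n_keep, Lc), dr_s2k(n_keep, K), dr_pi(n_keep, K);
  vec dr_s2(n_keep), dr_size(n_keep), dr_lp(n_keep);
  mat dr_om;
  if (store_omega) dr_om.set_size(n_keep, J);
  mat dr_yhat;
  if (Nv > 0) dr_yhat.set_size(n_keep, Nv);

  int keep = 0;
  for (int t = 0; t < T; ++t) {
    // (1) outcome augmentation
    if (outcome_type == 1) {
      for (int n = 0; n < N; ++n) {
        double mu = ystar[n] - r[n];
        double ynew = (y_obs[n] > 0.5) ? rtnorm_lower1(mu, 1.0, 0.0)
                                       : rtnorm_upper1(mu, 1.0, 0.0);
        r[n] += ynew - ystar[n];
        ystar[n] = ynew;
      }
    } else if (outcome_type == 2) {
      double sd = std::sqrt(sigma2);
      for (int n = 0; n < N; ++n) {
        if (event[n] == 1) continue; // ystar fixed at log y
        double mu = ystar[n] - r[n];
        double ynew = rtnorm_lower1(mu, sd, std::log(y_obs[n]));
        r[n] += ynew - ystar[n];
        ystar[n] = ynew;
      }
    }

    // (2) imputation of block-missing rows
    for (int idx : misE) {
      for (int k = 0; k < K; ++k) {
        double e_old = E(idx, k);
        double bB = beta_B[k];
        double rho = r[idx] + e_old * bB;
        double mean, var;
        impute_e_moments(xM(idx, k), sigma2_k[k], bB, rho, sigma2,
                         modular_imp, mean, var);
        double e_new = mean + std::sqrt(var) * R::norm_rand();
        E(idx, k) = e_new;
        r[idx] = rho - e_new * bB;
      }
    }
    for (int idx : misM) {
      for (int j = 0; j < J; ++j) {
        int k = gene_of[j];
        double om_j = omega[j];
        double bk = beta_M[k] - beta_B[k];
        double m_old = M(idx, j);
        double mech_res = E(idx, k) - xM(idx, k);
        double e_part = mech_res + m_old * om_j;
        double rho = r[idx] + m_old * om_j * bk;
        double mean, var;
        impute_m_moments(sigma_m[j] * sigma_m[j], om_j, sigma2_k[k],
                         e_part, bk, rho, sigma2, modular_imp, mean, var);
        double m_new = mean + std::sqrt(var) * R::norm_rand();
        M(idx, j) = m_new;
        xM(idx, k) += (m_new - m_old) * om_j;
        r[idx] = rho - m_new * om_j * bk;
      }
    }

    for (int half = 0; half < 2; ++half) {
      bool do_mech = (half == 0) != clin_first;
      if (do_mech) {
        // (3) mechanistic block
        for (int k = 0; k < K; ++k) {
          double bk = beta_M[k] - beta_B[k];
          bool couple = !modular_mech && bk != 0.0;
          mat Mk = M.cols(Jk[k]);
          vec Rk = couple ? vec(r + bk * xM.col(k)) : vec(N, arma::fill::zeros);
          arma::ivec zk = z.elem(arma::conv_to<uvec>::from(Jk[k]));
          vec omk = omega.elem(Jk[k]);
          mech_gene_core(Mk, E.col(k), Rk, zk, omk, sigma2_k[k], pi_k[k],
                         bk, sigma2, couple, tau_k[k], a, b, d1, d2,
                         true, true);
          z.elem(arma::conv_to<uvec>::from(Jk[k])) = zk;
          omega.elem(Jk[k]) = omk;
          vec xM_new = Mk * omk;
          if (bk != 0.0) r += bk * (xM.col(k) - xM_new);
          xM.col(k) = xM_new;
        }
      } else {
        // (4) clinical block
        for (int k = 0; k < K; ++k) {
          vec xMk = xM.col(k);
          vec xBk = E.col(k) - xMk;
          vec s = r + beta_M[k] * xMk + beta_B[k] * xBk;
          double nb = 0.0;
          for (arma::uword t2 = 0; t2 < nbr[k].n_elem; ++t2) {
            int k2 = nbr[k][t2];
            if (gamma_M[k2] == 1 || gamma_B[k2] == 1) nb += 1.0;
          }
          double prior_logit = d + f * nb;
          int gM, gB; double bM, bB;
          clin_gene_core(xMk, xBk, s, prior_logit, log_alloc, tau, sigma2,
                         gM, gB, bM, bB);
          gamma_M[k] = gM; gamma_B[k] = gB;
          beta_M[k] = bM; beta_B[k] = bB;
          r = s - bM * xMk - bB * xBk;
        }
        // beta_C joint draw
        {
          vec sC = r + C * beta_C;
          mat A = C.t() * C;
          A.diag() += tau_c;
          mat L = arma::chol(A, "lower");
          vec h = C.t() * sC;
          vec m = arma::solve(arma::trimatu(L.t()),
                              arma::solve(arma::trimatl(L), h));
          vec zr(Lc);
          for (int l = 0; l < Lc; ++l) zr[l] = R::norm_rand();
          vec bC_new = m + std::sqrt(sigma2) *
                           arma::solve(arma::trimatu(L.t()), zr);
          r = sC - C * bC_new;
          beta_C = bC_new;
        }
        // sigma^2 (held at 1 for the probit case)
        if (outcome_type != 1) {
          int qb = 0; double ssb = 0.0;
          for (int k = 0; k < K; ++k) {
            if (gamma_M[k] == 1) { ++qb; ssb += beta_M[k] * beta_M[k]; }
            if (gamma_B[k] == 1) { ++qb; ssb += beta_B[k] * beta_B[k]; }
          }
          double rate = d2 + 0.5 * arma::dot(r, r) +
                        0.5 * (tau * ssb + tau_c * arma::dot(beta_C, beta_C));
          sigma2 = 1.0 / R::rgamma(d1 + 0.5 * (N + Lc + qb), 1.0 / rate);
        }
      }
    }

    // successive-conditional ("getting it right") mode: regenerate the data
    // from the current parameters, keeping M and C fixed
    if (geweke) {
      for (int k = 0; k < K; ++k) {
        double sd = std::sqrt(sigma2_k[k]);
        for (int n = 0; n < N; ++n)
          E(n, k) = xM(n, k) + sd * R::norm_rand();
      }
      vec mu = C * beta_C;
      for (int k = 0; k < K; ++k) {
        if (beta_B[k] != 0.0) mu += beta_B[k] * (E.col(k) - xM.col(k));
        if (beta_M[k] != 0.0) mu += beta_M[k] * xM.col(k);
      }
      double sd = std::sqrt(sigma2);
      for (int n = 0; n < N; ++n) ystar[n] = mu[n] + sd * R::norm_rand();
      r = ystar - mu;
    }

    if ((t + 1) % 200 == 0) recompute_resid(r); // guard against drift

    if (t >= Tb && (t - Tb) % thin == 0) {
      for (int k = 0; k < K; ++k) {
        dr_gM(keep, k) = gamma_M[k];
        dr_gB(keep, k) = gamma_B[k];
        dr_bM(keep, k) = beta_M[k];
        dr_bB(keep, k) = beta_B[k];
        dr_s2k(keep, k) = sigma2_k[k];
        dr_pi(keep, k) = pi_k[k];
      }
      for (int j = 0; j < J; ++j) dr_z(keep, j) = z[j];
      for (int l = 0; l < Lc; ++l) dr_bC(keep, l) = beta_C[l];
      dr_s2[keep] = sigma2;
      dr_size[keep] = arma::accu(gamma_M) + arma::accu(gamma_B);
      if (store_omega) for (int j = 0; j < J; ++j) dr_om(keep, j) = omega[j];

      // log joint density up to normalizing constants
      {
        double lp = -0.5 * N * std::log(sigma2) -
                    arma::dot(r, r) / (2.0 * sigma2);
        for (int k = 0; k < K; ++k) {
          vec res = E.col(k) - xM.col(k);
          lp += -0.5 * N * std::log(sigma2_k[k]) -
                arma::dot(res, res) / (2.0 * sigma2_k[k]);
        }
        double gsum = 0.0, gpair = 0.0;
        for (int k = 0; k < K; ++k) {
          int g = (gamma_M[k] == 1 || gamma_B[k] == 1) ? 1 : 0;
          gsum += g;
          if (g)
            for (arma::uword t2 = 0; t2 < nbr[k].n_elem; ++t2) {
              int k2 = nbr[k][t2];
              if (gamma_M[k2] == 1 || gamma_B[k2] == 1) gpair += 0.5;
            }
        }
        lp += d * gsum + f * gpair; // each active linked pair counts once
        dr_lp[keep] = lp;
      }

      if (Nv > 0) {
        vec yh = C_new * beta_C;
        for (int k = 0; k < K; ++k) {
          if (beta_M[k] == 0.0 && beta_B[k] == 0.0) continue;
          vec xMn = M_new.cols(Jk[k]) * omega.elem(Jk[k]);
          yh += beta_M[k] * xMn + beta_B[k] * (E_new.col(k) - xMn);
        }
        for (int v = 0; v < Nv; ++v) dr_yhat(keep, v) = yh[v];
      }
      ++keep;
    }

    if (verbose && (t + 1) % 1000 == 0)
      Rcpp::Rcerr << "iter " << (t + 1) << "/" << T << " model size "
                  << (arma::accu(gamma_M) + arma::accu(gamma_B)) << "\n";
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["gamma_M"] = dr_gM, _["gamma_Mbar"] = dr_gB,
      _["beta_M"] = dr_bM, _["beta_Mbar"] = dr_bB,
      _["z"] = dr_z, _["beta_C"] = dr_bC,
      _["sigma2"] = dr_s2, _["sigma2_k"] = dr_s2k, _["pi_k"] = dr_pi,
      _["model_size"] = dr_size, _["log_post"] = dr_lp);
  if (store_omega) out["omega"] = dr_om;
  if (Nv > 0) out["yhat"] = dr_yhat;
  return out;
}
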