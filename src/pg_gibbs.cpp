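// Polya-Gamma Gibbs sampler for a bivariate (right/left eye) binary-outcome
// GLMM with a two-component Gaussian-mixture random-intercept pair, plus the
// adaptive Gauss-Hermite marginal likelihood used by the discriminant.
//
// Parameterisation: no fixed intercept column; the per-eye intercepts live in
// the mixture-component means, so means and fixed effects stay identifiable.
// All randomness comes from R's RNG (RNGScope), so set.seed() governs draws.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TRUNC = 0.64;  // series/IG truncation point (Devroye)

// alternating-series coefficients of the Jacobi J*(1,0) density
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC)
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// P(proposal falls in the truncated-exponential branch); log-scale for safety
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double X = TRUNC + 1.0;
  if (TRUNC * z < 1.0) {  // mu > TRUNC: chi-square style rejection
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / TRUNC);
      X = TRUNC / ((1.0 + TRUNC * E1) * (1.0 + TRUNC * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    double mu = 1.0 / z;
    while (X > TRUNC) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY -
          0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// exact PG(1, z) draw (Devroye rejection from the tilted Jacobi density)
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  for (;;) {
    double X;
    if (R::unif_rand() < mass_texpon(z))
      X = TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(z);
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

static inline double lse_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// -2 * Bernoulli log-likelihood of both eye series given eta
static double cond_deviance(const arma::vec& etaR, const arma::vec& etaL,
                            const arma::vec& yR, const arma::vec& yL) {
  double ll = 0.0;
  for (arma::uword j = 0; j < etaR.n_elem; ++j) {
    ll += yR[j] * etaR[j] - lse_log1pexp(etaR[j]);
    ll += yL[j] * etaL[j] - lse_log1pexp(etaL[j]);
  }
  return -2.0 * ll;
}

// draw from N(mean, P^{-1}) for 2x2 precision P
static arma::vec rmvnorm_prec2(const arma::vec& rhs, const arma::mat& P) {
  arma::mat U = arma::chol(P);  // upper: P = U'U
  arma::vec mean = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec zdraw(2);
  zdraw[0] = R::norm_rand();
  zdraw[1] = R::norm_rand();
  return mean + arma::solve(arma::trimatu(U), zdraw);
}

// inverse-Wishart(df, S) draw via Bartlett on the Wishart of S^{-1}
static arma::mat riwish2(double df, const arma::mat& S) {
  arma::mat Sinv = arma::inv_sympd(S);
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::norm_rand();
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();  // ~ Wishart(df, Sinv)
  return arma::inv_sympd(W);
}

static double log_dmvnorm2(const arma::vec& x, const arma::vec& m,
                           const arma::mat& Sinv, double logdetS) {
  arma::vec d = x - m;
  double q = arma::as_scalar(d.t() * Sinv * d);
  return -std::log(2.0 * M_PI) - 0.5 * logdetS - 0.5 * q;
}

// Gibbs sampler.  X: n_obs x p design (no intercept); yR/yL in {0,1};
// pid: 0-based patient index, rows grouped by patient.
// [[Rcpp::export]]
List pg_mixture_gibbs_cpp(const arma::mat& X, const arma::vec& yR,
                          const arma::vec& yL, const arma::ivec& pid,
                          int n_pat, int n_iter, int burnin, int thin,
                          double beta_prior_var, double mean_prior_var,
                          double iw_df, double iw_scale_diag,
                          double dirichlet_alpha, bool share_beta,
                          const arma::vec& beta_init,
                          const arma::mat& mu_init) {
  const int n_obs = X.n_rows, p = X.n_cols, K = 2;

  // row range per patient (rows are grouped)
  arma::ivec row_start(n_pat, arma::fill::value(-1)), row_end(n_pat);
  for (int j = 0; j < n_obs; ++j) {
    int i = pid[j];
    if (row_start[i] < 0) row_start[i] = j;
    row_end[i] = j;
  }

  // state
  arma::vec betaR = beta_init, betaL = beta_init;
  arma::mat b(n_pat, 2, arma::fill::zeros);
  arma::ivec z(n_pat);
  arma::vec w(K, arma::fill::value(1.0 / K));
  arma::mat mu = mu_init;  // K x 2
  arma::cube Sig(2, 2, K), Siginv(2, 2, K);
  for (int k = 0; k < K; ++k) {
    Sig.slice(k) = arma::eye(2, 2);
    Siginv.slice(k) = arma::eye(2, 2);
    }
  for (int i = 0; i < n_pat; ++i) {
    z[i] = (R::unif_rand() < 0.5) ? 0 : 1;
    b(i, 0) = mu(z[i], 0) + R::norm_rand();
    b(i, 1) = mu(z[i], 1) + R::norm_rand();
  }

  arma::vec kapR = yR - 0.5, kapL = yL - 0.5;
  arma::mat prior_prec_beta = arma::eye(p, p) / beta_prior_var;
  arma::mat S0 = arma::eye(2, 2) * iw_scale_diag;

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat keep_betaR(n_keep, p), keep_betaL(n_keep, p);
  arma::mat keep_w(n_keep, K), keep_mu(n_keep, 2 * K), keep_sig(n_keep, 3 * K);
  arma::vec keep_dev(n_keep);
  arma::vec sum_betaR(p, arma::fill::zeros), sum_betaL(p, arma::fill::zeros);
  arma::mat sum_b(n_pat, 2, arma::fill::zeros);

  arma::vec etaR(n_obs), etaL(n_obs), omR(n_obs), omL(n_obs);
  int stored = 0;

  for (int it = 0; it < n_iter; ++it) {
    // linear predictors and PG draws
    arma::vec xbR = X * betaR, xbL = X * betaL;
    for (int j = 0; j < n_obs; ++j) {
      int i = pid[j];
      etaR[j] = xbR[j] + b(i, 0);
      etaL[j] = xbL[j] + b(i, 1);
      omR[j] = rpg1(etaR[j]);
      omL[j] = rpg1(etaL[j]);
    }

    // fixed effects, sampled from their conditional with the random
    // intercepts integrated out analytically (the PG-augmented model is
    // jointly Gaussian in (beta, b) given omega and z, so the marginal is
    // available in closed form).  Patient-level effects would otherwise mix
    // extremely slowly against the flexible intercept distribution.
    if (p > 0) {
      const int dim = share_beta ? p : 2 * p;
      arma::mat Prec(dim, dim, arma::fill::zeros);
      Prec.submat(0, 0, p - 1, p - 1) = prior_prec_beta;
      if (!share_beta) Prec.submat(p, p, dim - 1, dim - 1) = prior_prec_beta;
      arma::vec lin(dim, arma::fill::zeros);
      const double* xmem = X.memptr();  // column-major
      arma::vec cxR(p), cxL(p);
      for (int i = 0; i < n_pat; ++i) {
        int k = z[i];
        double swR = 0.0, swL = 0.0, skR = 0.0, skL = 0.0;
        cxR.zeros();
        cxL.zeros();
        for (int j = row_start[i]; j <= row_end[i]; ++j) {
          swR += omR[j];
          swL += omL[j];
          skR += kapR[j];
          skL += kapL[j];
          for (int a = 0; a < p; ++a) {
            double xa = xmem[a * n_obs + j];
            cxR[a] += omR[j] * xa;
            cxL[a] += omL[j] * xa;
            lin[a] += kapR[j] * xa;
            lin[share_beta ? a : p + a] += kapL[j] * xa;
            if (share_beta) {
              for (int c = a; c < p; ++c)
                Prec(a, c) += (omR[j] + omL[j]) * xa * xmem[c * n_obs + j];
            } else {
              for (int c = a; c < p; ++c) {
                double xc = xmem[c * n_obs + j];
                Prec(a, c) += omR[j] * xa * xc;
                Prec(p + a, p + c) += omL[j] * xa * xc;
              }
            }
          }
        }
        arma::mat D = Siginv.slice(k);
        D(0, 0) += swR;
        D(1, 1) += swL;
        arma::mat A = arma::inv_sympd(D);
        arma::vec v = Siginv.slice(k) * mu.row(k).t();
        v[0] += skR;
        v[1] += skL;
        arma::vec Av = A * v;
        if (share_beta) {
          // U_i = [cxR cxL]; subtract U A U' and U A v
          for (int a = 0; a < p; ++a) {
            lin[a] -= cxR[a] * Av[0] + cxL[a] * Av[1];
            for (int c = a; c < p; ++c)
              Prec(a, c) -= A(0, 0) * cxR[a] * cxR[c] +
                            A(0, 1) * (cxR[a] * cxL[c] + cxL[a] * cxR[c]) +
                            A(1, 1) * cxL[a] * cxL[c];
          }
        } else {
          for (int a = 0; a < p; ++a) {
            lin[a] -= cxR[a] * Av[0];
            lin[p + a] -= cxL[a] * Av[1];
            for (int c = a; c < p; ++c) {
              Prec(a, c) -= A(0, 0) * cxR[a] * cxR[c];
              Prec(p + a, p + c) -= A(1, 1) * cxL[a] * cxL[c];
            }
            for (int c = 0; c < p; ++c)
              Prec(a, p + c) -= A(0, 1) * cxR[a] * cxL[c];
          }
        }
      }
      Prec = arma::symmatu(Prec);
      arma::mat U = arma::chol(Prec);
      arma::vec mean = arma::solve(arma::trimatu(U),
                                   arma::solve(arma::trimatl(U.t()), lin));
      arma::vec zd(dim);
      for (int d = 0; d < dim; ++d) zd[d] = R::norm_rand();
      arma::vec bdraw = mean + arma::solve(arma::trimatu(U), zd);
      if (share_beta) {
        betaR = bdraw;
        betaL = bdraw;
      } else {
        betaR = bdraw.subvec(0, p - 1);
        betaL = bdraw.subvec(p, dim - 1);
      }
      xbR = X * betaR;
      xbL = X * betaL;
    }

    // random-intercept pairs, conditional on the new fixed effects
    for (int i = 0; i < n_pat; ++i) {
      int k = z[i];
      double swR = 0.0, swL = 0.0, cR = 0.0, cL = 0.0;
      for (int j = row_start[i]; j <= row_end[i]; ++j) {
        swR += omR[j];
        swL += omL[j];
        cR += kapR[j] - omR[j] * xbR[j];
        cL += kapL[j] - omL[j] * xbL[j];
      }
      arma::mat P = Siginv.slice(k);
      P(0, 0) += swR;
      P(1, 1) += swL;
      arma::vec rhs = Siginv.slice(k) * mu.row(k).t();
      rhs[0] += cR;
      rhs[1] += cL;
      arma::vec bi = rmvnorm_prec2(rhs, P);
      b(i, 0) = bi[0];
      b(i, 1) = bi[1];
    }

    // component indicators
    arma::vec logdet(K);
    for (int k = 0; k < K; ++k) {
      double val, sign;
      arma::log_det(val, sign, Sig.slice(k));
      logdet[k] = val;
    }
    arma::ivec nk(K, arma::fill::zeros);
    for (int i = 0; i < n_pat; ++i) {
      double l0 = std::log(w[0]) +
                  log_dmvnorm2(b.row(i).t(), mu.row(0).t(), Siginv.slice(0), logdet[0]);
      double l1 = std::log(w[1]) +
                  log_dmvnorm2(b.row(i).t(), mu.row(1).t(), Siginv.slice(1), logdet[1]);
      double m = std::max(l0, l1);
      double p1 = std::exp(l1 - m) / (std::exp(l0 - m) + std::exp(l1 - m));
      z[i] = (R::unif_rand() < p1) ? 1 : 0;
      nk[z[i]] += 1;
    }

    // weights
    double g0 = R::rgamma(dirichlet_alpha + nk[0], 1.0);
    double g1 = R::rgamma(dirichlet_alpha + nk[1], 1.0);
    w[0] = g0 / (g0 + g1);
    w[1] = 1.0 - w[0];

    // component means and covariances
    for (int k = 0; k < K; ++k) {
      arma::vec bsum(2, arma::fill::zeros);
      for (int i = 0; i < n_pat; ++i)
        if (z[i] == k) bsum += b.row(i).t();
      arma::mat P = (double)nk[k] * Siginv.slice(k) +
                    arma::eye(2, 2) / mean_prior_var;
      arma::vec rhs = Siginv.slice(k) * bsum;
      arma::vec mk = rmvnorm_prec2(rhs, P);
      mu(k, 0) = mk[0];
      mu(k, 1) = mk[1];

      arma::mat Sc = S0;
      for (int i = 0; i < n_pat; ++i)
        if (z[i] == k) {
          arma::vec d = b.row(i).t() - mk;
          Sc += d * d.t();
        }
      Sig.slice(k) = riwish2(iw_df + nk[k], Sc);
      Siginv.slice(k) = arma::inv_sympd(Sig.slice(k));
    }

    // store
    if (it >= burnin && (it - burnin) % thin == 0) {
      arma::vec xbR2 = X * betaR, xbL2 = X * betaL;
      arma::vec eR(n_obs), eL(n_obs);
      for (int j = 0; j < n_obs; ++j) {
        int i = pid[j];
        eR[j] = xbR2[j] + b(i, 0);
        eL[j] = xbL2[j] + b(i, 1);
      }
      keep_dev[stored] = cond_deviance(eR, eL, yR, yL);
      keep_betaR.row(stored) = betaR.t();
      keep_betaL.row(stored) = betaL.t();
      keep_w.row(stored) = w.t();
      keep_mu(stored, 0) = mu(0, 0);
      keep_mu(stored, 1) = mu(0, 1);
      keep_mu(stored, 2) = mu(1, 0);
      keep_mu(stored, 3) = mu(1, 1);
      for (int k = 0; k < K; ++k) {
        keep_sig(stored, 3 * k + 0) = Sig.slice(k)(0, 0);
        keep_sig(stored, 3 * k + 1) = Sig.slice(k)(0, 1);
        keep_sig(stored, 3 * k + 2) = Sig.slice(k)(1, 1);
      }
      sum_betaR += betaR;
      sum_betaL += betaL;
      sum_b += b;
      ++stored;
    }
  }

  // deviance at the (within-chain) posterior mean of beta and b
  arma::vec mbR = sum_betaR / stored, mbL = sum_betaL / stored;
  arma::mat mb = sum_b / stored;
  arma::vec xbR = X * mbR, xbL = X * mbL, eR(n_obs), eL(n_obs);
  for (int j = 0; j < n_obs; ++j) {
    int i = pid[j];
    eR[j] = xbR[j] + mb(i, 0);
    eL[j] = xbL[j] + mb(i, 1);
  }
  double dev_at_mean = cond_deviance(eR, eL, yR, yL);

  return List::create(
      _["beta_right"] = keep_betaR, _["beta_left"] = keep_betaL,
      _["weights"] = keep_w, _["means"] = keep_mu, _["covs"] = keep_sig,
      _["deviance"] = keep_dev, _["b_mean"] = mb,
      _["dev_at_mean"] = dev_at_mean);
}

// conditional deviance at supplied parameters (used for the pooled
// penalized-expected-deviance plug-in term)
// [[Rcpp::export]]
double conditional_deviance_cpp(const arma::mat& X, const arma::vec& yR,
                                const arma::vec& yL, const arma::ivec& pid,
                                const arma::vec& betaR, const arma::vec& betaL,
                                const arma::mat& b) {
  arma::vec xbR = X * betaR, xbL = X * betaL;
  int n_obs = X.n_rows;
  arma::vec eR(n_obs), eL(n_obs);
  for (int j = 0; j < n_obs; ++j) {
    int i = pid[j];
    eR[j] = xbR[j] + b(i, 0);
    eL[j] = xbL[j] + b(i, 1);
  }
  return cond_deviance(eR, eL, yR, yL);
}

// ---------------------------------------------------------------------------
// Marginal log-likelihood of each patient's bivariate grade history under a
// mixture-of-normals random-intercept model, by adaptive Gauss-Hermite
// quadrature centred on the per-component conditional mode.

struct PatBlock {
  arma::mat xbRL;  // n_j x 2 fixed-effect parts
  arma::mat y;     // n_j x 2
};

static double cond_loglik_b(const PatBlock& pb, double bR, double bL) {
  double ll = 0.0;
  for (arma::uword j = 0; j < pb.y.n_rows; ++j) {
    double eR = pb.xbRL(j, 0) + bR, eL = pb.xbRL(j, 1) + bL;
    ll += pb.y(j, 0) * eR - lse_log1pexp(eR);
    ll += pb.y(j, 1) * eL - lse_log1pexp(eL);
  }
  return ll;
}

// [[Rcpp::export]]
arma::vec marginal_loglik_cpp(const arma::mat& X, const arma::vec& yR,
                              const arma::vec& yL, const arma::ivec& pid,
                              int n_pat, const arma::vec& betaR,
                              const arma::vec& betaL, const arma::vec& w,
                              const arma::mat& mu, const arma::mat& sig_flat,
                              const arma::vec& gh_x, const arma::vec& gh_w) {
  const int K = w.n_elem, Q = gh_x.n_elem;
  arma::vec xbR = X * betaR, xbL = X * betaL;
  arma::vec out(n_pat, arma::fill::zeros);
  arma::vec log_ghw = arma::log(gh_w);

  // per-component covariance pieces
  std::vector<arma::mat> Sinv(K), L(K);
  std::vector<double> logdet(K);
  std::vector<bool> pointmass(K);
  for (int k = 0; k < K; ++k) {
    arma::mat S(2, 2);
    S(0, 0) = sig_flat(k, 0);
    S(0, 1) = S(1, 0) = sig_flat(k, 1);
    S(1, 1) = sig_flat(k, 2);
    pointmass[k] = arma::abs(S).max() < 1e-12;
    if (!pointmass[k]) {
      Sinv[k] = arma::inv_sympd(S);
      double val, sign;
      arma::log_det(val, sign, S);
      logdet[k] = val;
    }
  }

  arma::ivec row_start(n_pat, arma::fill::value(-1)), row_end(n_pat, arma::fill::value(-2));
  for (arma::uword j = 0; j < X.n_rows; ++j) {
    int i = pid[j];
    if (row_start[i] < 0) row_start[i] = j;
    row_end[i] = j;
  }

  for (int i = 0; i < n_pat; ++i) {
    int nj = row_end[i] - row_start[i] + 1;
    if (nj <= 0) {        // empty history: likelihood 1
      out[i] = 0.0;
      continue;
    }
    PatBlock pb;
    pb.xbRL.set_size(nj, 2);
    pb.y.set_size(nj, 2);
    for (int j = 0; j < nj; ++j) {
      int r = row_start[i] + j;
      pb.xbRL(j, 0) = xbR[r];
      pb.xbRL(j, 1) = xbL[r];
      pb.y(j, 0) = yR[r];
      pb.y(j, 1) = yL[r];
    }

    arma::vec logI(K);
    for (int k = 0; k < K; ++k) {
      arma::vec mk = mu.row(k).t();
      if (pointmass[k]) {
        logI[k] = cond_loglik_b(pb, mk[0], mk[1]);
        continue;
      }
      // Newton to the conditional mode (concave objective)
      arma::vec bc = mk;
      for (int itn = 0; itn < 60; ++itn) {
        arma::vec g(2, arma::fill::zeros);
        arma::mat H = Sinv[k];
        for (int j = 0; j < nj; ++j) {
          double pRj = 1.0 / (1.0 + std::exp(-(pb.xbRL(j, 0) + bc[0])));
          double pLj = 1.0 / (1.0 + std::exp(-(pb.xbRL(j, 1) + bc[1])));
          g[0] += pb.y(j, 0) - pRj;
          g[1] += pb.y(j, 1) - pLj;
          H(0, 0) += pRj * (1.0 - pRj);
          H(1, 1) += pLj * (1.0 - pLj);
        }
        g -= Sinv[k] * (bc - mk);
        arma::vec step = arma::solve(H, g);
        bc += step;
        if (arma::abs(step).max() < 1e-10) break;
      }
      // Hessian at the mode
      arma::mat H = Sinv[k];
      for (int j = 0; j < nj; ++j) {
        double pRj = 1.0 / (1.0 + std::exp(-(pb.xbRL(j, 0) + bc[0])));
        double pLj = 1.0 / (1.0 + std::exp(-(pb.xbRL(j, 1) + bc[1])));
        H(0, 0) += pRj * (1.0 - pRj);
        H(1, 1) += pLj * (1.0 - pLj);
      }
      arma::mat Hinv = arma::inv_sympd(H);
      arma::mat Lm = arma::chol(Hinv, "lower");
      double logdetL;
      {
        double val, sign;
        arma::log_det(val, sign, Lm);
        logdetL = val;
      }
      // sum over the tensor grid on the log scale
      double best = -arma::datum::inf;
      arma::mat logf(Q, Q);
      for (int qa = 0; qa < Q; ++qa) {
        for (int qb = 0; qb < Q; ++qb) {
          double u0 = gh_x[qa], u1 = gh_x[qb];
          arma::vec uu = {u0, u1};
          arma::vec bq = bc + std::sqrt(2.0) * (Lm * uu);
          arma::vec d = bq - mk;
          double lprior = -std::log(2.0 * M_PI) - 0.5 * logdet[k] -
                          0.5 * arma::as_scalar(d.t() * Sinv[k] * d);
          double lf = cond_loglik_b(pb, bq[0], bq[1]) + lprior +
                      log_ghw[qa] + log_ghw[qb] + u0 * u0 + u1 * u1;
          logf(qa, qb) = lf;
          if (lf > best) best = lf;
        }
      }
      double s = 0.0;
      for (int qa = 0; qa < Q; ++qa)
        for (int qb = 0; qb < Q; ++qb) s += std::exp(logf(qa, qb) - best);
      logI[k] = std::log(2.0) + logdetL + best + std::log(s);
    }
    // mixture combine
    double best = -arma::datum::inf;
    for (int k = 0; k < K; ++k) {
      double v = std::log(w[k]) + logI[k];
      if (v > best) best = v;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(std::log(w[k]) + logI[k] - best);
    out[i] = best + std::log(s);
  }
  return out;
}
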