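// Adaptive MCMC for the two mixed-model families:
//   beta family:     y_i ~ Beta(mu_i * delta_i, (1 - mu_i) * delta_i),
//                    logit(mu_i) = x_i' beta + R_{r_i} + S_{s_i},
//                    log(delta_i) = gamma0 + gamma1 * log(n_i)
//   gaussian family: y_i ~ Normal(x_i' beta + R_{r_i} + S_{s_i}, 1 / tau_i),
//                    log(tau_i) = gamma0 + gamma1 * log(n_i)
// Priors: beta, gamma normal; S ~ MVN(0, sigma_S^2 * C) through the
// precision P = C^{-1}; R ~ intrinsic CAR(tau_R, W) with the overall level
// transferred to the intercept each sweep; sigma_S half-normal; tau_R
// gamma (conjugate Gibbs given R).
//
// Moves per iteration:
//   * joint adaptive-Metropolis block for beta (Haario-style empirical
//     covariance, scale adapted toward 25% acceptance)
//   * joint adaptive block for (gamma0, gamma1)
//   * scalar random-walk updates for each S_j and R_j (local likelihood)
//   * log-scale walk for sigma_S; Gibbs for tau_R
//   * directional "confound" moves exchanging each latitude-type column
//     of X against the compensating per-region profile of that column:
//     beta_c += t, R_k -= t * mean(X[, c] | region k). These traverse the
//     near-flat ridge between smooth spatial effects and latitude terms
//     that single-site updates cross only very slowly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double ll_one(int family, double y, double eta, double ld) {
  if (family == 0) {
    double mu = 1.0 / (1.0 + std::exp(-eta));
    double delta = std::exp(ld);
    return R::dbeta(y, mu * delta, (1.0 - mu) * delta, 1);
  }
  return R::dnorm(y, eta, std::exp(-0.5 * ld), 1);
}

// [[Rcpp::export]]
List run_mcmc_chain(int family, arma::vec y, arma::mat X, arma::vec logn,
                    IntegerVector sp, IntegerVector reg, arma::mat P,
                    IntegerVector ci, IntegerVector cj, NumericVector cw,
                    int car_rank, IntegerVector confound_cols,
                    List prior, List settings, List init) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int T = P.n_rows;
  const bool has_region = reg.size() > 0;

  const double beta_sd = as<double>(prior["beta_sd"]);
  const double gamma_sd = as<double>(prior["gamma_sd"]);
  const double hs = as<double>(prior["sigma_s_scale"]);
  const double tr_shape = as<double>(prior["tau_r_shape"]);
  const double tr_rate = as<double>(prior["tau_r_rate"]);

  const int n_iter = as<int>(settings["iterations"]);
  const int burnin = as<int>(settings["burnin"]);
  const int thin = as<int>(settings["thin"]);

  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::vec gam = as<arma::vec>(init["gamma"]);
  arma::vec S = as<arma::vec>(init["S"]);
  arma::vec R_eff = as<arma::vec>(init["R"]);
  double lss = std::log(as<double>(init["sigma_s"]));
  double tau_r = as<double>(init["tau_r"]);
  const int K = R_eff.n_elem;

  std::vector<std::vector<int>> by_sp(T), by_reg(std::max(K, 1));
  for (int i = 0; i < n; ++i) {
    by_sp[sp[i] - 1].push_back(i);
    if (has_region) by_reg[reg[i] - 1].push_back(i);
  }
  std::vector<std::vector<std::pair<int, double>>> nb(std::max(K, 1));
  for (int e = 0; e < ci.size(); ++e) {
    nb[ci[e] - 1].push_back({cj[e] - 1, cw[e]});
    nb[cj[e] - 1].push_back({ci[e] - 1, cw[e]});
  }

  // per-region means of the confounded design columns
  const int nconf = has_region ? confound_cols.size() : 0;
  arma::mat conf_prof(std::max(K, 1), std::max(nconf, 1), arma::fill::zeros);
  for (int c = 0; c < nconf; ++c) {
    int col = confound_cols[c] - 1;
    for (int k = 0; k < K; ++k) {
      if (by_reg[k].empty()) continue;
      double m = 0;
      for (int i : by_reg[k]) m += X(i, col);
      conf_prof(k, c) = m / by_reg[k].size();
    }
  }
  // per-species means of every design column (species-ridge moves)
  arma::mat sp_prof(T, p, arma::fill::zeros);
  for (int j = 0; j < T; ++j) {
    if (by_sp[j].empty()) continue;
    for (int c = 0; c < p; ++c) {
      double m = 0;
      for (int i : by_sp[j]) m += X(i, c);
      sp_prof(j, c) = m / by_sp[j].size();
    }
  }

  arma::vec eta = X * beta;
  for (int i = 0; i < n; ++i) {
    eta[i] += S[sp[i] - 1];
    if (has_region) eta[i] += R_eff[reg[i] - 1];
  }
  arma::vec ld = gam[0] + gam[1] * logn;
  arma::vec llv(n);
  for (int i = 0; i < n; ++i) llv[i] = ll_one(family, y[i], eta[i], ld[i]);
  if (!llv.is_finite())
    stop("non-finite log-likelihood at initialisation (observation %d)",
         (int)llv.index_min() + 1);
  double ll_sum = arma::accu(llv);
  arma::vec tP = P * S;            // running P * S
  double qS = arma::dot(S, tP);    // running S' P S

  // CAR prior quadratic form helper
  auto car_quad = [&](const arma::vec &R) {
    double q = 0;
    for (int e = 0; e < ci.size(); ++e) {
      double d = R[ci[e] - 1] - R[cj[e] - 1];
      q += cw[e] * d * d;
    }
    return q;
  };

  // adaptive blocks: empirical mean/covariance for beta and gamma
  arma::vec mu_b = beta, mu_g = gam;
  arma::mat cov_b(p, p, arma::fill::eye), cov_g(2, 2, arma::fill::eye);
  cov_b *= 0.01; cov_g *= 0.01;
  double lsc_b = std::log(2.38 / std::sqrt((double)p)),
         lsc_g = std::log(2.38 / std::sqrt(2.0));
  arma::vec st_sp_conf(p, arma::fill::value(0.2)),
      ac_sp_conf(p, arma::fill::zeros);
  double st_lss = 0.3;
  arma::vec st_S(T, arma::fill::value(0.3));
  arma::vec st_R(std::max(K, 1), arma::fill::value(0.3));
  arma::vec st_conf(std::max(nconf, 1), arma::fill::value(0.2));
  double ac_b = 0, ac_g = 0, ac_lss = 0;
  arma::vec ac_S(T, arma::fill::zeros), ac_R(std::max(K, 1), arma::fill::zeros),
      ac_conf(std::max(nconf, 1), arma::fill::zeros);
  const int batch = 50;
  int batch_no = 0;

  const int kept = (n_iter - burnin) / thin;
  const int npar = p + 2 + T + 1 + (has_region ? K + 1 : 0);
  arma::mat draws(kept, npar);
  arma::vec ll_store(kept);
  arma::mat llobs_store(kept, n);
  int row = 0;

  arma::vec scratch(n), eta_new(n), ld_new(n);

  auto full_eval = [&](const arma::vec &eta_c, const arma::vec &ld_c) {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      scratch[i] = ll_one(family, y[i], eta_c[i], ld_c[i]);
      s += scratch[i];
    }
    return s;
  };
  auto rnorm_vec = [&](int d) {
    arma::vec z(d);
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    return z;
  };

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed-effect block ---
    {
      arma::mat cb = cov_b + 1e-8 * arma::eye(p, p);
      arma::mat Lc = arma::chol(cb, "lower");
      arma::vec cand = beta + std::exp(lsc_b) * (Lc * rnorm_vec(p));
      eta_new = eta + X * (cand - beta);
      double ll_new = full_eval(eta_new, ld);
      double dlp = 0;
      for (int j = 0; j < p; ++j)
        dlp += R::dnorm(cand[j], 0.0, beta_sd, 1) -
               R::dnorm(beta[j], 0.0, beta_sd, 1);
      if (std::log(R::unif_rand()) < ll_new - ll_sum + dlp) {
        beta = cand; eta = eta_new; llv = scratch; ll_sum = ll_new;
        ac_b += 1;
      }
    }
    // --- dispersion block ---
    {
      arma::mat cg = cov_g + 1e-8 * arma::eye(2, 2);
      arma::mat Lc = arma::chol(cg, "lower");
      arma::vec cand = gam + std::exp(lsc_g) * (Lc * rnorm_vec(2));
      ld_new = cand[0] + cand[1] * logn;
      double ll_new = full_eval(eta, ld_new);
      double dlp = 0;
      for (int j = 0; j < 2; ++j)
        dlp += R::dnorm(cand[j], 0.0, gamma_sd, 1) -
               R::dnorm(gam[j], 0.0, gamma_sd, 1);
      if (std::log(R::unif_rand()) < ll_new - ll_sum + dlp) {
        gam = cand; ld = ld_new; llv = scratch; ll_sum = ll_new;
        ac_g += 1;
      }
    }
    // --- species effects ---
    double sigma2 = std::exp(2.0 * lss);
    for (int j = 0; j < T; ++j) {
      double d = st_S[j] * R::norm_rand();
      double s0 = S[j], s1 = s0 + d;
      double cross = tP[j] - P(j, j) * s0;
      double dq = P(j, j) * (s1 * s1 - s0 * s0) + 2.0 * d * cross;
      double dll = -0.5 * dq / sigma2;
      double dll_data = 0;
      for (int i : by_sp[j])
        dll_data += ll_one(family, y[i], eta[i] + d, ld[i]) - llv[i];
      if (std::log(R::unif_rand()) < dll + dll_data) {
        S[j] = s1;
        qS += dq;
        tP += P.col(j) * d;
        for (int i : by_sp[j]) {
          eta[i] += d;
          double nll = ll_one(family, y[i], eta[i], ld[i]);
          ll_sum += nll - llv[i];
          llv[i] = nll;
        }
        ac_S[j] += 1;
      }
    }
    // --- species scale ---
    {
      double cand = lss + st_lss * R::norm_rand();
      double s0 = std::exp(lss), s1 = std::exp(cand);
      double lp1 = -(T - 1.0) * cand - 0.5 * qS / (s1 * s1) -
                   0.5 * s1 * s1 / (hs * hs);
      double lp0 = -(T - 1.0) * lss - 0.5 * qS / (s0 * s0) -
                   0.5 * s0 * s0 / (hs * hs);
      if (std::log(R::unif_rand()) < lp1 - lp0) { lss = cand; ac_lss += 1; }
    }
    // --- directional moves along the fixed-effect/species ridge ---
    sigma2 = std::exp(2.0 * lss);
    for (int c = 0; c < p; ++c) {
      double t = st_sp_conf[c] * R::norm_rand();
      arma::vec S_cand = S - t * sp_prof.col(c);
      double b0 = beta[c], b1 = b0 + t;
      for (int i = 0; i < n; ++i)
        eta_new[i] = eta[i] + t * (X(i, c) - sp_prof(sp[i] - 1, c));
      double ll_new = full_eval(eta_new, ld);
      arma::vec tP_cand = P * S_cand;
      double qS_cand = arma::dot(S_cand, tP_cand);
      double dlp = R::dnorm(b1, 0.0, beta_sd, 1) -
                   R::dnorm(b0, 0.0, beta_sd, 1) -
                   0.5 * (qS_cand - qS) / sigma2;
      if (std::log(R::unif_rand()) < ll_new - ll_sum + dlp) {
        beta[c] = b1; S = S_cand; tP = tP_cand; qS = qS_cand;
        eta = eta_new; llv = scratch; ll_sum = ll_new;
        ac_sp_conf[c] += 1;
      }
    }
    // --- region effects, confound moves, spatial precision ---
    if (has_region) {
      for (int j = 0; j < K; ++j) {
        double d = st_R[j] * R::norm_rand();
        double r0 = R_eff[j], r1 = r0 + d;
        double dpr = 0;
        if (nb[j].empty()) {  // isolated region: independent-normal fallback
          dpr = r1 * r1 - r0 * r0;
        } else {
          for (auto &e : nb[j]) {
            double a1 = r1 - R_eff[e.first], a0 = r0 - R_eff[e.first];
            dpr += e.second * (a1 * a1 - a0 * a0);
          }
        }
        double dll = -0.5 * tau_r * dpr;
        for (int i : by_reg[j])
          dll += ll_one(family, y[i], eta[i] + d, ld[i]) - llv[i];
        if (std::log(R::unif_rand()) < dll) {
          R_eff[j] = r1;
          for (int i : by_reg[j]) {
            eta[i] += d;
            double nll = ll_one(family, y[i], eta[i], ld[i]);
            ll_sum += nll - llv[i];
            llv[i] = nll;
          }
          ac_R[j] += 1;
        }
      }
      // directional moves along the latitude/region ridge
      for (int c = 0; c < nconf; ++c) {
        int col = confound_cols[c] - 1;
        double t = st_conf[c] * R::norm_rand();
        arma::vec R_cand = R_eff - t * conf_prof.col(c);
        double b0 = beta[col], b1 = b0 + t;
        for (int i = 0; i < n; ++i)
          eta_new[i] = eta[i] + t * (X(i, col) - conf_prof(reg[i] - 1, c));
        double ll_new = full_eval(eta_new, ld);
        double dlp = R::dnorm(b1, 0.0, beta_sd, 1) -
                     R::dnorm(b0, 0.0, beta_sd, 1) -
                     0.5 * tau_r * (car_quad(R_cand) - car_quad(R_eff));
        if (std::log(R::unif_rand()) < ll_new - ll_sum + dlp) {
          beta[col] = b1; R_eff = R_cand;
          eta = eta_new; llv = scratch; ll_sum = ll_new;
          ac_conf[c] += 1;
        }
      }
      // transfer the overall level to the intercept (identifiability)
      double m = arma::mean(R_eff);
      R_eff -= m;
      beta[0] += m;
      // conjugate gamma update for the spatial precision
      tau_r = R::rgamma(tr_shape + 0.5 * car_rank,
                        1.0 / (tr_rate + 0.5 * car_quad(R_eff)));
    }

    // --- adaptation (burn-in only) ---
    if (it < burnin) {
      double w = 1.0 / (it + 2.0);   // running moments for the blocks
      arma::vec db = beta - mu_b;
      mu_b += w * db;
      cov_b = (1 - w) * cov_b + w * (db * db.t());
      arma::vec dg = gam - mu_g;
      mu_g += w * dg;
      cov_g = (1 - w) * cov_g + w * (dg * dg.t());
      if ((it + 1) % batch == 0) {
        ++batch_no;
        double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
        auto tune = [&](double &lstep, double &acc, double target) {
          lstep += (acc / batch > target ? delta : -delta);
          acc = 0;
        };
        tune(lsc_b, ac_b, 0.25);
        tune(lsc_g, ac_g, 0.25);
        double tmp;
        for (int c = 0; c < p; ++c) {
          tmp = std::log(st_sp_conf[c]); tune(tmp, ac_sp_conf[c], 0.44);
          st_sp_conf[c] = std::exp(tmp);
        }
        tmp = std::log(st_lss); tune(tmp, ac_lss, 0.44); st_lss = std::exp(tmp);
        for (int j = 0; j < T; ++j) {
          tmp = std::log(st_S[j]); tune(tmp, ac_S[j], 0.44);
          st_S[j] = std::exp(tmp);
        }
        if (has_region) {
          for (int j = 0; j < K; ++j) {
            tmp = std::log(st_R[j]); tune(tmp, ac_R[j], 0.44);
            st_R[j] = std::exp(tmp);
          }
          for (int c = 0; c < nconf; ++c) {
            tmp = std::log(st_conf[c]); tune(tmp, ac_conf[c], 0.44);
            st_conf[c] = std::exp(tmp);
          }
        }
      }
    }

    // --- storage ---
    if (it >= burnin && (it - burnin + 1) % thin == 0 && row < kept) {
      int c = 0;
      for (int j = 0; j < p; ++j) draws(row, c++) = beta[j];
      draws(row, c++) = gam[0];
      draws(row, c++) = gam[1];
      for (int j = 0; j < T; ++j) draws(row, c++) = S[j];
      draws(row, c++) = std::exp(lss);
      if (has_region) {
        for (int j = 0; j < K; ++j) draws(row, c++) = R_eff[j];
        draws(row, c++) = tau_r;
      }
      ll_store[row] = ll_sum;
      llobs_store.row(row) = llv.t();
      ++row;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = ll_store,
                      _["loglik_obs"] = llobs_store);
}
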