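// Metropolis-within-Gibbs sampler for the phylogenetic multi-species
// occupancy model.
//
// Model: Z[i,k] ~ Bern(psi[i,k]), logit(psi) = alpha_k + x_i' beta_k;
// Y[m][i,k] ~ Binomial(N[m][i], p[m][k] * Z[i,k]) for masked-in species;
// beta_j ~ MVN(W gamma_j, sigma_j^2 * (lambda_j C_t + (1 - lambda_j) I));
// alpha_k ~ N(mu_alpha, sigma_alpha^2); logit p[m][k] ~ N(mu_p[m], sigma_p[m]^2);
// lambda_j ~ 0.5 * delta_0 + 0.5 * U(0,1) (spike and slab); t ~ uniform over
// the candidate tree set, refreshed by a Metropolis move each iteration.
//
// The per-tree correlation matrices enter through their eigendecompositions
// (V, d), so the lambda transform costs O(K) per density evaluation:
// lambda C + (1-lambda) I = V diag(lambda d + 1 - lambda) V'.
//
// All randomness comes from R's RNG (RNGScope), so set.seed() in R gives
// bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double softplus(double x) {
  // log(1 + exp(x)), stable
  double m = x > 0 ? x : 0.0;
  return m + std::log1p(std::exp(-std::fabs(x)));
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// half-normal(0, scale) log density for s > 0 (constant dropped)
static inline double dhalfnorm_log(double s, double scale) {
  if (s <= 0) return -INFINITY;
  double z = s / scale;
  return -0.5 * z * z;
}

// beta-prior log density pieces for covariate j given eigenvalues d of C_t:
// returns -0.5 * sum(log e) - quad / (2 sigma^2) - K log sigma, with
// e_i = lambda d_i + 1 - lambda and quad = sum w_i^2 / e_i, w = V'(beta - m).
static double beta_prior_logdens(const arma::vec& w, const arma::vec& d,
                                 double lambda, double sigma, double* quad_out) {
  double logdet = 0.0, quad = 0.0;
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    double e = lambda * d[i] + (1.0 - lambda);
    if (e < 1e-12) return -INFINITY;
    logdet += std::log(e);
    quad += w[i] * w[i] / e;
  }
  if (quad_out) *quad_out = quad;
  return -0.5 * logdet - quad / (2.0 * sigma * sigma) -
         double(w.n_elem) * std::log(sigma);
}

struct Adapt {
  arma::vec ls;      // log step sizes
  double target;
  Adapt(arma::uword n, double init, double target_) :
    ls(n, arma::fill::value(std::log(init))), target(target_) {}
  inline double step(arma::uword i) const { return std::exp(ls[i]); }
  inline void tune(arma::uword i, double acc_prob, int iter, bool frozen) {
    if (frozen) return;
    ls[i] += std::pow(iter + 1.0, -0.6) * (acc_prob - target);
    if (ls[i] < -8) ls[i] = -8;
    if (ls[i] > 4) ls[i] = 4;
  }
};

// [[Rcpp::export(name = ".pom_mcmc_cpp")]]
List pom_mcmc_cpp(arma::cube Y,          // I x K x M season-detection counts
                  arma::mat Nmat,        // I x M seasons surveyed
                  arma::umat mask,       // K x M
                  arma::mat X,           // I x J covariates (standardized)
                  arma::cube V,          // K x K x T eigenvectors per tree
                  arma::mat dmat,        // K x T eigenvalues per tree
                  arma::mat W,           // K x (P+1) trait design, col 1 = 1
                  int n_iter, int burn, int thin,
                  bool prior_only,
                  bool update_occ_params, bool update_det_params,
                  bool update_lambda, bool update_tree,
                  double sd_hyper, double sd_sigma, double spike,
                  List init) {
  const arma::uword I = Y.n_rows, K = Y.n_cols, M = Y.n_slices;
  const arma::uword J = X.n_cols, T = V.n_slices, P1 = W.n_cols;
  RNGScope scope;

  // ---- state ------------------------------------------------------------
  arma::vec alpha = as<arma::vec>(init["alpha"]);          // K
  arma::mat beta  = as<arma::mat>(init["beta"]);           // K x J
  arma::mat gamma = as<arma::mat>(init["gamma"]);          // P1 x J
  arma::vec sigma = as<arma::vec>(init["sigma"]);          // J
  double mu_alpha = as<double>(init["mu_alpha"]);
  double sigma_alpha = as<double>(init["sigma_alpha"]);
  arma::mat lp    = as<arma::mat>(init["lp"]);             // K x M (logit p)
  arma::vec mu_p  = as<arma::vec>(init["mu_p"]);           // M
  arma::vec sigma_p = as<arma::vec>(init["sigma_p"]);      // M
  arma::vec lambda = as<arma::vec>(init["lambda"]);        // J
  arma::mat Z     = as<arma::mat>(init["Z"]);              // I x K
  int tree = as<int>(init["tree"]);                        // 0-based

  // ---- data caches ------------------------------------------------------
  arma::umat anyY(I, K, arma::fill::zeros);
  for (arma::uword m = 0; m < M; ++m)
    for (arma::uword k = 0; k < K; ++k)
      if (mask(k, m))
        for (arma::uword i = 0; i < I; ++i)
          if (Y(i, k, m) > 0) anyY(i, k) = 1;
  for (arma::uword i = 0; i < I; ++i)
    for (arma::uword k = 0; k < K; ++k)
      if (anyY(i, k)) Z(i, k) = 1.0;   // detections force occupancy

  // linear predictor and beta-prior caches; SL = softplus(L) kept in sync
  arma::mat L = X * beta.t();
  L.each_row() += alpha.t();
  arma::mat SL(I, K);
  for (arma::uword k = 0; k < K; ++k)
    for (arma::uword i = 0; i < I; ++i) SL(i, k) = softplus(L(i, k));
  arma::vec sp_prop(I);                            // proposal scratch
  arma::mat A = V.slice(tree).t() * W;            // K x P1
  arma::mat wj(K, J);                              // V'(beta_j - W gamma_j)
  arma::vec quad(J);
  for (arma::uword j = 0; j < J; ++j) {
    wj.col(j) = V.slice(tree).t() * beta.col(j) - A * gamma.col(j);
    quad[j] = 0; // refreshed below
  }
  arma::vec p = arma::vec(K * M);                  // natural-scale p cache
  arma::mat pmat(K, M);
  for (arma::uword m = 0; m < M; ++m)
    for (arma::uword k = 0; k < K; ++k)
      pmat(k, m) = 1.0 / (1.0 + std::exp(-lp(k, m)));

  // ---- adaptation -------------------------------------------------------
  // species blocks (alpha_k, beta_{.,k}) are proposed jointly: one
  // occupancy-likelihood evaluation per species per sweep
  Adapt ad_blk(K, 0.3, 0.25),
        ad_lp(K * M, 0.5, 0.35), ad_sigma(J, 0.4, 0.35),
        ad_siga(1, 0.4, 0.35), ad_sigp(M, 0.4, 0.35),
        ad_lam(J, 0.2, 0.35),
        ad_shift(J + 1 + M, 1.0, 0.35), // translation moves (recentering)
        ad_scale(J + 1 + M, 0.3, 0.35); // scaling moves (deviations + SD)

  // ---- storage ----------------------------------------------------------
  const int n_keep = (n_iter - burn) / thin;
  arma::mat s_alpha(n_keep, K), s_mu(n_keep, J), s_sigma(n_keep, J),
            s_lambda(n_keep, J);
  arma::cube s_beta(n_keep, K, J), s_gamma(n_keep, P1, J), s_lp(n_keep, K, M);
  arma::vec s_mu_alpha(n_keep), s_sigma_alpha(n_keep);
  arma::mat s_mu_p(n_keep, M), s_sigma_p(n_keep, M);
  arma::ivec s_tree(n_keep);
  arma::ucube s_Z(I, K, n_keep);
  arma::mat acc_count(5, 2, arma::fill::zeros); // [moves][acc, prop] post-burn

  // (1-p)^n lookup tables per method/species, n = 0..Nmax
  const int Nmax = (int)Nmat.max();
  arma::cube pow1mp(K, M, Nmax + 1);
  arma::imat Nint(I, M);
  for (arma::uword m = 0; m < M; ++m)
    for (arma::uword i = 0; i < I; ++i) Nint(i, m) = (int)Nmat(i, m);

  int kept = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    const bool frozen = iter >= burn;
    const arma::vec dcur = dmat.col(tree);

    // ---- (1) Z Gibbs ----------------------------------------------------
    if (!prior_only) {
      for (arma::uword m = 0; m < M; ++m) {
        for (arma::uword k = 0; k < K; ++k) {
          double v = 1.0;
          for (int n = 0; n <= Nmax; ++n) {
            pow1mp(k, m, n) = v;
            v *= (1.0 - pmat(k, m));
          }
        }
      }
    }
    for (arma::uword k = 0; k < K; ++k) {
      for (arma::uword i = 0; i < I; ++i) {
        if (anyY(i, k)) { Z(i, k) = 1.0; continue; }
        double psi = 1.0 / (1.0 + std::exp(-L(i, k)));
        double pr;
        if (prior_only) {
          pr = psi;
        } else {
          double q = 1.0;
          for (arma::uword m = 0; m < M; ++m)
            if (mask(k, m)) q *= pow1mp(k, m, Nint(i, m));
          pr = psi * q / (psi * q + 1.0 - psi);
        }
        Z(i, k) = (unif_rand() < pr) ? 1.0 : 0.0;
      }
    }

    if (update_occ_params) {
      // ---- (2) species blocks (alpha_k, beta_{., k}) jointly -----------
      arma::vec delta(J + 1), Lp(I);
      for (arma::uword k = 0; k < K; ++k) {
        double s = ad_blk.step(k);
        for (arma::uword j = 0; j <= J; ++j) delta[j] = s * norm_rand();
        double dll = dnorm_log(alpha[k] + delta[0], mu_alpha, sigma_alpha) -
                     dnorm_log(alpha[k], mu_alpha, sigma_alpha);
        bool ok = true;
        for (arma::uword j = 0; j < J && ok; ++j) {
          double dquad = 0.0;
          for (arma::uword r = 0; r < K; ++r) {
            double e = lambda[j] * dcur[r] + (1.0 - lambda[j]);
            if (e < 1e-12) { ok = false; break; }
            double wn = wj(r, j) + delta[j + 1] * V(k, r, tree);
            dquad += (wn * wn - wj(r, j) * wj(r, j)) / e;
          }
          dll -= dquad / (2.0 * sigma[j] * sigma[j]);
        }
        if (!ok) continue;
        if (!prior_only) {
          for (arma::uword i = 0; i < I; ++i) {
            double dL = delta[0];
            for (arma::uword j = 0; j < J; ++j) dL += delta[j + 1] * X(i, j);
            Lp[i] = L(i, k) + dL;
            sp_prop[i] = softplus(Lp[i]);
            dll += Z(i, k) * dL - sp_prop[i] + SL(i, k);
          }
        }
        double ap = std::min(1.0, std::exp(dll));
        if (unif_rand() < ap) {
          alpha[k] += delta[0];
          for (arma::uword j = 0; j < J; ++j) {
            beta(k, j) += delta[j + 1];
            for (arma::uword r = 0; r < K; ++r)
              wj(r, j) += delta[j + 1] * V(k, r, tree);
          }
          if (!prior_only) {
            L.col(k) = Lp;
            SL.col(k) = sp_prop;
          } else {
            L.col(k) += delta[0];
            for (arma::uword j = 0; j < J; ++j)
              L.col(k) += delta[j + 1] * X.col(j);
          }
          if (frozen) acc_count(0, 0) += 1;
        }
        if (frozen) acc_count(0, 1) += 1;
        ad_blk.tune(k, ap, iter, frozen);
      }

      // ---- (3) translation moves ---------------------------------------
      // shift a whole species-level block and its hypermean jointly; the
      // hierarchical deviations (and hence the phylogenetic prior term) are
      // invariant, so these moves decorrelate the hyper-level random walk.
      // Cheap without a likelihood; rationed to every 10th sweep with one.
      if (prior_only || iter % 10 == 0) {
        for (arma::uword j = 0; j < J; ++j) {          // beta_j + gamma_0j
          double del = ad_shift.step(j) * norm_rand();
          double dll = dnorm_log(gamma(0, j) + del, 0.0, sd_hyper) -
                       dnorm_log(gamma(0, j), 0.0, sd_hyper);
          if (!prior_only) {
            for (arma::uword k = 0; k < K; ++k)
              for (arma::uword i = 0; i < I; ++i) {
                double Lp2 = L(i, k) + del * X(i, j);
                dll += Z(i, k) * del * X(i, j) - softplus(Lp2) + SL(i, k);
              }
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            gamma(0, j) += del;
            beta.col(j) += del;
            for (arma::uword k = 0; k < K; ++k) {
              L.col(k) += del * X.col(j);
              if (!prior_only)
                for (arma::uword i = 0; i < I; ++i)
                  SL(i, k) = softplus(L(i, k));
            }
          }
          ad_shift.tune(j, ap, iter, frozen);
        }
        {                                              // alpha + mu_alpha
          double del = ad_shift.step(J) * norm_rand();
          double dll = dnorm_log(mu_alpha + del, 0.0, sd_hyper) -
                       dnorm_log(mu_alpha, 0.0, sd_hyper);
          if (!prior_only) {
            for (arma::uword k = 0; k < K; ++k)
              for (arma::uword i = 0; i < I; ++i)
                dll += Z(i, k) * del - softplus(L(i, k) + del) + SL(i, k);
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            mu_alpha += del;
            alpha += del;
            L += del;
            if (!prior_only)
              for (arma::uword k = 0; k < K; ++k)
                for (arma::uword i = 0; i < I; ++i)
                  SL(i, k) = softplus(L(i, k));
          }
          ad_shift.tune(J, ap, iter, frozen);
        }
      }

      // ---- (3b) scaling moves ------------------------------------------
      // multiply a block's deviations from its hypermean and the hyper-SD by
      // a common lognormal factor c; the hierarchical density contributes
      // only c * p(c sigma)/p(sigma) after the Jacobian, so these moves let
      // the scale hierarchy mix at prior speed.
      if (prior_only || iter % 10 == 0) {
        for (arma::uword j = 0; j < J; ++j) {
          double c = std::exp(ad_scale.step(j) * norm_rand());
          double dll = std::log(c) + dhalfnorm_log(c * sigma[j], sd_sigma) -
                       dhalfnorm_log(sigma[j], sd_sigma);
          arma::vec bnew;
          if (!prior_only) {
            bnew = W * gamma.col(j) + c * (beta.col(j) - W * gamma.col(j));
            for (arma::uword k = 0; k < K; ++k) {
              double db = bnew[k] - beta(k, j);
              for (arma::uword i = 0; i < I; ++i) {
                double dL = db * X(i, j);
                dll += Z(i, k) * dL - softplus(L(i, k) + dL) + SL(i, k);
              }
            }
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            if (prior_only)
              bnew = W * gamma.col(j) + c * (beta.col(j) - W * gamma.col(j));
            for (arma::uword k = 0; k < K; ++k) {
              double db = bnew[k] - beta(k, j);
              beta(k, j) = bnew[k];
              for (arma::uword i = 0; i < I; ++i) {
                L(i, k) += db * X(i, j);
                if (!prior_only) SL(i, k) = softplus(L(i, k));
              }
            }
            wj.col(j) *= c;
            sigma[j] *= c;
          }
          ad_scale.tune(j, ap, iter, frozen);
        }
        {                                              // alpha block
          double c = std::exp(ad_scale.step(J) * norm_rand());
          double dll = std::log(c) + dhalfnorm_log(c * sigma_alpha, sd_sigma) -
                       dhalfnorm_log(sigma_alpha, sd_sigma);
          arma::vec anew = mu_alpha + c * (alpha - mu_alpha);
          if (!prior_only) {
            for (arma::uword k = 0; k < K; ++k) {
              double da = anew[k] - alpha[k];
              for (arma::uword i = 0; i < I; ++i)
                dll += Z(i, k) * da - softplus(L(i, k) + da) + SL(i, k);
            }
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            for (arma::uword k = 0; k < K; ++k) {
              double da = anew[k] - alpha[k];
              for (arma::uword i = 0; i < I; ++i) {
                L(i, k) += da;
                if (!prior_only) SL(i, k) = softplus(L(i, k));
              }
            }
            alpha = anew;
            sigma_alpha *= c;
          }
          ad_scale.tune(J, ap, iter, frozen);
        }
      }

      // ---- (4) gamma_j Gibbs (normal-normal in the eigenbasis) ----------
      for (arma::uword j = 0; j < J; ++j) {
        arma::vec einv(K);
        for (arma::uword r = 0; r < K; ++r) {
          double e = lambda[j] * dcur[r] + (1.0 - lambda[j]);
          einv[r] = 1.0 / e;
        }
        arma::vec u = wj.col(j) + A * gamma.col(j);      // V' beta_j
        arma::mat Ae = A.each_col() % einv;              // diag(1/e) A
        arma::mat Prec = (A.t() * Ae) / (sigma[j] * sigma[j]);
        Prec.diag() += 1.0 / (sd_hyper * sd_hyper);
        arma::vec b = (Ae.t() * u) / (sigma[j] * sigma[j]);
        arma::mat R = arma::chol(Prec);                  // upper
        arma::vec mean = arma::solve(Prec, b);
        arma::vec z(P1);
        for (arma::uword r = 0; r < P1; ++r) z[r] = norm_rand();
        gamma.col(j) = mean + arma::solve(arma::trimatu(R), z);
        wj.col(j) = u - A * gamma.col(j);
      }

      // ---- (5) hyperparameters for alpha --------------------------------
      {
        double prec = K / (sigma_alpha * sigma_alpha) + 1.0 / (sd_hyper * sd_hyper);
        double mean = (arma::accu(alpha) / (sigma_alpha * sigma_alpha)) / prec;
        mu_alpha = mean + norm_rand() / std::sqrt(prec);

        double lsd = std::log(sigma_alpha);
        double prop = std::exp(lsd + ad_siga.step(0) * norm_rand());
        double cur_ll = dhalfnorm_log(sigma_alpha, sd_sigma) + std::log(sigma_alpha);
        double prop_ll = dhalfnorm_log(prop, sd_sigma) + std::log(prop);
        for (arma::uword k = 0; k < K; ++k) {
          cur_ll += dnorm_log(alpha[k], mu_alpha, sigma_alpha);
          prop_ll += dnorm_log(alpha[k], mu_alpha, prop);
        }
        double ap = std::min(1.0, std::exp(prop_ll - cur_ll));
        if (unif_rand() < ap) sigma_alpha = prop;
        ad_siga.tune(0, ap, iter, frozen);
      }

      // ---- (6) sigma_j --------------------------------------------------
      for (arma::uword j = 0; j < J; ++j) {
        double q;
        double cur = beta_prior_logdens(wj.col(j), dcur, lambda[j], sigma[j], &q);
        quad[j] = q;
        double prop = std::exp(std::log(sigma[j]) + ad_sigma.step(j) * norm_rand());
        double cur_t = cur + dhalfnorm_log(sigma[j], sd_sigma) + std::log(sigma[j]);
        double prop_t = beta_prior_logdens(wj.col(j), dcur, lambda[j], prop, nullptr) +
                        dhalfnorm_log(prop, sd_sigma) + std::log(prop);
        double ap = std::min(1.0, std::exp(prop_t - cur_t));
        if (unif_rand() < ap) sigma[j] = prop;
        ad_sigma.tune(j, ap, iter, frozen);
      }
    }

    // ---- (7) spike-and-slab lambda_j ------------------------------------
    if (update_lambda) {
      for (arma::uword j = 0; j < J; ++j) {
        double cur_dens = beta_prior_logdens(wj.col(j), dcur, lambda[j],
                                             sigma[j], nullptr);
        if (lambda[j] == 0.0) {
          // spike -> slab: draw from U(0,1); reverse move picked w.p. 1/2
          double prop = unif_rand();
          double la = beta_prior_logdens(wj.col(j), dcur, prop, sigma[j], nullptr) -
                      cur_dens + std::log(0.5);
          if (std::log(unif_rand()) < la) lambda[j] = prop;
          if (frozen) { acc_count(2, 1) += 1; if (lambda[j] != 0.0) acc_count(2, 0) += 1; }
        } else if (unif_rand() < 0.5) {
          // slab -> spike
          double la = beta_prior_logdens(wj.col(j), dcur, 0.0, sigma[j], nullptr) -
                      cur_dens + std::log(2.0);
          if (std::log(unif_rand()) < la) lambda[j] = 0.0;
          if (frozen) { acc_count(2, 1) += 1; if (lambda[j] == 0.0) acc_count(2, 0) += 1; }
        } else {
          // reflected random walk within (0, 1]
          double prop = lambda[j] + ad_lam.step(j) * norm_rand();
          for (int r = 0; r < 64 && (prop < 0.0 || prop > 1.0); ++r) {
            if (prop < 0.0) prop = -prop;
            if (prop > 1.0) prop = 2.0 - prop;
          }
          if (prop <= 0.0) prop = 1e-12;
          double la = beta_prior_logdens(wj.col(j), dcur, prop, sigma[j], nullptr) -
                      cur_dens;
          double ap = std::min(1.0, std::exp(la));
          if (unif_rand() < ap) lambda[j] = prop;
          ad_lam.tune(j, ap, iter, frozen);
          if (frozen) { acc_count(3, 1) += 1; if (lambda[j] == prop) acc_count(3, 0) += 1; }
        }
      }
    }

    // ---- (8) tree index -------------------------------------------------
    if (update_tree && T > 1) {
      int prop_t = (int)std::floor(unif_rand() * T);
      if (prop_t >= (int)T) prop_t = T - 1;
      if (prop_t != tree) {
        const arma::vec dprop = dmat.col(prop_t);
        arma::mat Aprop = V.slice(prop_t).t() * W;
        arma::mat wprop(K, J);
        double la = 0.0;
        for (arma::uword j = 0; j < J; ++j) {
          wprop.col(j) = V.slice(prop_t).t() * beta.col(j) - Aprop * gamma.col(j);
          la += beta_prior_logdens(wprop.col(j), dprop, lambda[j], sigma[j], nullptr) -
                beta_prior_logdens(wj.col(j), dcur, lambda[j], sigma[j], nullptr);
        }
        if (frozen) acc_count(4, 1) += 1;
        if (std::log(unif_rand()) < la) {
          tree = prop_t;
          A = Aprop;
          wj = wprop;
          if (frozen) acc_count(4, 0) += 1;
        }
      }
    }

    // ---- (9) detection parameters ---------------------------------------
    if (update_det_params) {
      for (arma::uword m = 0; m < M; ++m) {
        arma::uword n_in = 0;
        double sum_lp = 0.0;
        arma::vec SNv(K, arma::fill::zeros), SYv(K, arma::fill::zeros);
        for (arma::uword k = 0; k < K; ++k) {
          if (!mask(k, m)) continue;
          n_in += 1;
          double SN = 0.0, SY = 0.0;
          if (!prior_only) {
            for (arma::uword i = 0; i < I; ++i) {
              if (Z(i, k) > 0.5) { SN += Nmat(i, m); SY += Y(i, k, m); }
            }
          }
          SNv[k] = SN; SYv[k] = SY;
          arma::uword idx = m * K + k;
          double prop = lp(k, m) + ad_lp.step(idx) * norm_rand();
          double cur_ll = dnorm_log(lp(k, m), mu_p[m], sigma_p[m]);
          double prop_ll = dnorm_log(prop, mu_p[m], sigma_p[m]);
          if (!prior_only && SN > 0) {
            cur_ll += -SY * softplus(-lp(k, m)) - (SN - SY) * softplus(lp(k, m));
            prop_ll += -SY * softplus(-prop) - (SN - SY) * softplus(prop);
          }
          double ap = std::min(1.0, std::exp(prop_ll - cur_ll));
          if (unif_rand() < ap) {
            lp(k, m) = prop;
            pmat(k, m) = 1.0 / (1.0 + std::exp(-prop));
          }
          ad_lp.tune(idx, ap, iter, frozen);
          sum_lp += lp(k, m);
        }
        // translation move: shift all masked logits and mu_p together
        if (n_in > 0 && (prior_only || iter % 10 == 0)) {
          double del = ad_shift.step(J + 1 + m) * norm_rand();
          double dll = dnorm_log(mu_p[m] + del, 0.0, sd_hyper) -
                       dnorm_log(mu_p[m], 0.0, sd_hyper);
          if (!prior_only) {
            for (arma::uword k = 0; k < K; ++k) {
              if (!mask(k, m) || SNv[k] <= 0) continue;
              double l0 = lp(k, m), l1 = lp(k, m) + del;
              dll += -SYv[k] * softplus(-l1) - (SNv[k] - SYv[k]) * softplus(l1)
                     + SYv[k] * softplus(-l0) + (SNv[k] - SYv[k]) * softplus(l0);
            }
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            mu_p[m] += del;
            sum_lp = 0.0;
            for (arma::uword k = 0; k < K; ++k) {
              if (!mask(k, m)) continue;
              lp(k, m) += del;
              pmat(k, m) = 1.0 / (1.0 + std::exp(-lp(k, m)));
              sum_lp += lp(k, m);
            }
          }
          ad_shift.tune(J + 1 + m, ap, iter, frozen);
        }
        // scaling move: rescale logit deviations and sigma_p together
        if (n_in > 0 && (prior_only || iter % 10 == 0)) {
          double c = std::exp(ad_scale.step(J + 1 + m) * norm_rand());
          double dll = std::log(c) + dhalfnorm_log(c * sigma_p[m], sd_sigma) -
                       dhalfnorm_log(sigma_p[m], sd_sigma);
          arma::vec lnew(K);
          for (arma::uword k = 0; k < K; ++k) {
            if (!mask(k, m)) continue;
            lnew[k] = mu_p[m] + c * (lp(k, m) - mu_p[m]);
            if (!prior_only && SNv[k] > 0) {
              dll += -SYv[k] * softplus(-lnew[k]) - (SNv[k] - SYv[k]) * softplus(lnew[k])
                     + SYv[k] * softplus(-lp(k, m)) + (SNv[k] - SYv[k]) * softplus(lp(k, m));
            }
          }
          double ap = std::min(1.0, std::exp(dll));
          if (unif_rand() < ap) {
            sum_lp = 0.0;
            for (arma::uword k = 0; k < K; ++k) {
              if (!mask(k, m)) continue;
              lp(k, m) = lnew[k];
              pmat(k, m) = 1.0 / (1.0 + std::exp(-lp(k, m)));
              sum_lp += lp(k, m);
            }
            sigma_p[m] *= c;
          }
          ad_scale.tune(J + 1 + m, ap, iter, frozen);
        }
        if (n_in > 0) {
          double prec = n_in / (sigma_p[m] * sigma_p[m]) + 1.0 / (sd_hyper * sd_hyper);
          double mean = (sum_lp / (sigma_p[m] * sigma_p[m])) / prec;
          mu_p[m] = mean + norm_rand() / std::sqrt(prec);

          double prop = std::exp(std::log(sigma_p[m]) + ad_sigp.step(m) * norm_rand());
          double cur_t = dhalfnorm_log(sigma_p[m], sd_sigma) + std::log(sigma_p[m]);
          double prop_t = dhalfnorm_log(prop, sd_sigma) + std::log(prop);
          for (arma::uword k = 0; k < K; ++k) {
            if (!mask(k, m)) continue;
            cur_t += dnorm_log(lp(k, m), mu_p[m], sigma_p[m]);
            prop_t += dnorm_log(lp(k, m), mu_p[m], prop);
          }
          double ap = std::min(1.0, std::exp(prop_t - cur_t));
          if (unif_rand() < ap) sigma_p[m] = prop;
          ad_sigp.tune(m, ap, iter, frozen);
        }
      }
    }

    // ---- retention -------------------------------------------------------
    if (iter >= burn && (iter - burn) % thin == thin - 1) {
      if (kept < n_keep) {
        s_alpha.row(kept) = alpha.t();
        for (arma::uword j = 0; j < J; ++j) {
          s_beta.slice(j).row(kept) = beta.col(j).t();
          s_gamma.slice(j).row(kept) = gamma.col(j).t();
          s_mu(kept, j) = gamma(0, j);
          s_sigma(kept, j) = sigma[j];
          s_lambda(kept, j) = lambda[j];
        }
        s_mu_alpha[kept] = mu_alpha;
        s_sigma_alpha[kept] = sigma_alpha;
        for (arma::uword m = 0; m < M; ++m) {
          s_lp.slice(m).row(kept) = lp.col(m).t();
          s_mu_p(kept, m) = mu_p[m];
          s_sigma_p(kept, m) = sigma_p[m];
        }
        s_tree[kept] = tree;
        for (arma::uword k = 0; k < K; ++k)
          for (arma::uword i = 0; i < I; ++i)
            s_Z(i, k, kept) = Z(i, k) > 0.5 ? 1 : 0;
        kept += 1;
      }
    }
  }

  return List::create(
    _["alpha"] = s_alpha, _["beta"] = s_beta, _["gamma"] = s_gamma,
    _["mu"] = s_mu, _["sigma"] = s_sigma, _["lambda"] = s_lambda,
    _["mu_alpha"] = s_mu_alpha, _["sigma_alpha"] = s_sigma_alpha,
    _["lp"] = s_lp, _["mu_p"] = s_mu_p, _["sigma_p"] = s_sigma_p,
    _["tree"] = s_tree, _["Z"] = s_Z, _["acc"] = acc_count,
    _["n_keep"] = kept);
}
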