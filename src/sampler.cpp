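// Metropolis-Hastings-within-Gibbs sampler for the penalized homophily
// latent space model. The hot loop lives here; readable single-step R
// counterparts of every block are in R/mcmc-updates.R and are checked
// against this code at toy scale in the test suite.
//
// All randomness goes through R's RNG (norm_rand/unif_rand/R::rgamma...),
// so set.seed() in R makes a run bit-reproducible.
//
// Cached state, kept in sync across block updates:
//   D  — pairwise latent distances,
//   Cv — beta0 + sum_k beta_k X_k,
//   L  — log(1 + exp(eta)) with eta_ij = Cv_ij - D_ij / gamma_j.
// A pair's current log-probability is y*eta - L, which is exp-free; only
// proposal evaluations pay for exp().

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log(1 + exp(x)), overflow-safe; below -33.27 the value is < 4e-15 and
// treated as 0, above 33.28 it equals x to machine precision.
static inline double log1pexp_c(double x) {
  if (x <= -33.27) return 0.0;
  if (x >= 33.28) return x;
  return std::log1p(std::exp(x));
}

static inline double coldist(const arma::mat& Zt, int a, int b) {
  double s = 0.0;
  for (arma::uword k = 0; k < Zt.n_rows; ++k) {
    double diff = Zt(k, a) - Zt(k, b);
    s += diff * diff;
  }
  return std::sqrt(s);
}

static arma::mat procrustes_arma(const arma::mat& Z, const arma::mat& Zref) {
  arma::rowvec mz = arma::mean(Z, 0), mr = arma::mean(Zref, 0);
  arma::mat Zc = Z.each_row() - mz;
  arma::mat Rc = Zref.each_row() - mr;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, Zc.t() * Rc);
  arma::mat out = Zc * U * V.t();
  out.each_row() += mr;
  return out;
}

// nonzero covariate entry for the beta sweep
struct XEntry {
  int q;     // linear index i + n*j into Y, D, Cv, L
  int j;     // column (target node, selects gamma_j)
  double x;  // covariate value
  int y;     // observed edge
};

// [[Rcpp::export]]
List phlsm_mcmc_cpp(const arma::imat& Y, const arma::cube& X,
                    arma::mat Z, arma::vec beta, arma::vec gamma,
                    double sigma2, arma::vec pen,
                    const int penalty,        // 0 ridge, 1 lasso
                    const double beta0,
                    const double nu, const double phi,
                    const arma::vec& xi, const arma::vec& delta,
                    const arma::vec& alpha,
                    const int burn_in, const int monitor, const int thin,
                    const double M,
                    double step_z, double step_b,
                    const bool adapt, const bool use_lik,
                    const bool do_procrustes,
                    const arma::mat& Zref,
                    const int G,
                    arma::vec mix_w, arma::mat mix_mu, arma::vec mix_s2,
                    arma::ivec labels,
                    const double mu_prior_var,
                    const double s2_prior_a, const double s2_prior_b) {
  const int n = Y.n_rows;
  const int d = Z.n_cols;
  const int p = beta.n_elem;
  const int n_iter = burn_in + monitor;
  const int n_keep = (thin > 0) ? monitor / thin : 0;
  const bool mixture = (G > 1);

  arma::mat Zt = Z.t();                  // d x n, column-major node access

  arma::mat D(n, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < j; ++i) {
      double dd = coldist(Zt, i, j);
      D(i, j) = dd;
      D(j, i) = dd;
    }
  arma::mat Cv(n, n);
  Cv.fill(beta0);
  for (int k = 0; k < p; ++k) Cv += beta(k) * X.slice(k);
  arma::mat L(n, n, arma::fill::zeros), Lnew(n, n, arma::fill::zeros);
  if (use_lik)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (i != j) L(i, j) = log1pexp_c(Cv(i, j) - D(i, j) / gamma(j));

  // per-coefficient compact arrays of nonzero covariate entries
  std::vector<std::vector<XEntry>> xe(p);
  size_t max_e = 1;
  if (use_lik)
    for (int k = 0; k < p; ++k) {
      const arma::mat& Xk = X.slice(k);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          if (i != j && Xk(i, j) != 0.0)
            xe[k].push_back(XEntry{i + n * j, j, Xk(i, j), (int)Y(i, j)});
      max_e = std::max(max_e, xe[k].size());
    }
  std::vector<double> lscratch(max_e);

  // storage
  arma::cube Z_draws(n, d, n_keep > 0 ? n_keep : 1, arma::fill::zeros);
  arma::mat beta_draws(n_keep, p, arma::fill::zeros);
  arma::mat gamma_draws(n_keep, n, arma::fill::zeros);
  arma::vec sigma2_draws(n_keep > 0 ? n_keep : 1, arma::fill::zeros);
  arma::mat pen_draws(n_keep, p, arma::fill::zeros);
  arma::vec ll_trace(n_iter, arma::fill::zeros);
  arma::imat label_draws(mixture ? n_keep : 0, mixture ? n : 0);
  arma::mat mixw_draws(mixture ? n_keep : 0, mixture ? G : 0);
  arma::cube mixmu_draws(mixture ? G : 1, mixture ? d : 1,
                         mixture ? (n_keep > 0 ? n_keep : 1) : 1,
                         arma::fill::zeros);
  arma::mat mixs2_draws(mixture ? n_keep : 0, mixture ? G : 0);

  long acc_z = 0, try_z = 0, acc_b = 0, try_b = 0, acc_g = 0, try_g = 0;
  long win_acc_z = 0, win_try_z = 0, win_acc_b = 0, win_try_b = 0;

  arma::vec dnew(n), lnij(n), lnji(n), zprop(d);

  int keep = 0;
  for (int t = 1; t <= n_iter; ++t) {
    const bool monitoring = (t > burn_in);

    // ---- step 1: z random-walk sweep --------------------------------
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) zprop(k) = Zt(k, i) + step_z * norm_rand();
      double dlp = 0.0;
      if (use_lik) {
        const double inv_gi = 1.0 / gamma(i);
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dn = 0.0;
          for (int k = 0; k < d; ++k) {
            double diff = zprop(k) - Zt(k, j);
            dn += diff * diff;
          }
          dn = std::sqrt(dn);
          dnew(j) = dn;
          const double e0ij = Cv(i, j) - D(i, j) / gamma(j);
          const double e1ij = Cv(i, j) - dn / gamma(j);
          const double e0ji = Cv(j, i) - D(j, i) * inv_gi;
          const double e1ji = Cv(j, i) - dn * inv_gi;
          const double l1ij = log1pexp_c(e1ij);
          const double l1ji = log1pexp_c(e1ji);
          lnij(j) = l1ij;
          lnji(j) = l1ji;
          dlp += Y(i, j) * (e1ij - e0ij) - l1ij + L(i, j)
               + Y(j, i) * (e1ji - e0ji) - l1ji + L(j, i);
        }
      }
      // latent prior
      double sso = 0.0, ssn = 0.0;
      if (mixture) {
        const int g = labels(i);
        for (int k = 0; k < d; ++k) {
          double o = Zt(k, i) - mix_mu(g, k), nn = zprop(k) - mix_mu(g, k);
          sso += o * o;
          ssn += nn * nn;
        }
        dlp += (sso - ssn) / (2.0 * mix_s2(g));
      } else {
        for (int k = 0; k < d; ++k) {
          sso += Zt(k, i) * Zt(k, i);
          ssn += zprop(k) * zprop(k);
        }
        dlp += (sso - ssn) / (2.0 * sigma2);
      }
      if (monitoring) ++try_z; else ++win_try_z;
      if (std::log(unif_rand()) < dlp) {
        Zt.col(i) = zprop;
        if (use_lik)
          for (int j = 0; j < n; ++j)
            if (j != i) {
              D(i, j) = dnew(j); D(j, i) = dnew(j);
              L(i, j) = lnij(j); L(j, i) = lnji(j);
            }
        if (monitoring) ++acc_z; else ++win_acc_z;
      }
    }

    // Procrustes alignment to the reference (distances untouched)
    if (do_procrustes)
      Zt = procrustes_arma(Zt.t(), Zref).t();

    // ---- step 2: sigma2 Gibbs (plain Gaussian prior mode) -----------
    if (!mixture) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < d; ++k) ss += Zt(k, i) * Zt(k, i);
      sigma2 = 1.0 / R::rgamma(nu + n, 1.0 / (phi + 0.5 * ss));
    }

    // ---- step 3: beta random-walk sweep -----------------------------
    for (int k = 0; k < p; ++k) {
      const double bk = beta(k);
      double bprop;
      if (penalty == 0) bprop = bk + step_b * norm_rand();
      else {
        double e = R::exp_rand();
        bprop = bk + step_b * (unif_rand() < 0.5 ? -e : e);
      }
      const double db = bprop - bk;
      double dlp = 0.0;
      if (use_lik) {
        const std::vector<XEntry>& ek = xe[k];
        const double* cv = Cv.memptr();
        const double* dm = D.memptr();
        for (size_t a = 0; a < ek.size(); ++a) {
          const XEntry& e = ek[a];
          const double e0 = cv[e.q] - dm[e.q] / gamma(e.j);
          const double dx = db * e.x;
          const double e1 = e0 + dx;
          const double l1 = log1pexp_c(e1);
          lscratch[a] = l1;
          dlp += e.y * dx - l1 + L.memptr()[e.q];
        }
      }
      if (penalty == 0) dlp += -0.5 * pen(k) * (bprop * bprop - bk * bk);
      else dlp += -pen(k) * (std::fabs(bprop) - std::fabs(bk));
      if (monitoring) ++try_b; else ++win_try_b;
      if (std::log(unif_rand()) < dlp) {
        beta(k) = bprop;
        if (use_lik) {
          const std::vector<XEntry>& ek = xe[k];
          double* cv = Cv.memptr();
          double* lm = L.memptr();
          for (size_t a = 0; a < ek.size(); ++a) {
            cv[ek[a].q] += db * ek[a].x;
            lm[ek[a].q] = lscratch[a];
          }
        }
        if (monitoring) ++acc_b; else ++win_acc_b;
      }
    }

    // ---- step 4: penalty-parameter Gibbs ----------------------------
    for (int k = 0; k < p; ++k) {
      if (penalty == 0)
        pen(k) = R::rgamma(xi(k) + 0.5, 1.0 / (delta(k) + 0.5 * beta(k) * beta(k)));
      else
        pen(k) = R::rgamma(xi(k) + 1.0, 1.0 / (delta(k) + std::fabs(beta(k))));
    }

    // ---- step 5: gamma joint MH with Dirichlet proposal -------------
    {
      arma::vec gprop(n);
      double sg = 0.0;
      for (int j = 0; j < n; ++j) {
        gprop(j) = R::rgamma(M * gamma(j), 1.0);
        sg += gprop(j);
      }
      gprop /= sg;
      bool floored = false;
      for (int j = 0; j < n; ++j)
        if (gprop(j) < 1e-12) { gprop(j) = 1e-12; floored = true; }
      if (floored) gprop /= arma::accu(gprop);
      double dlp = 0.0;
      if (use_lik) {
        for (int j = 0; j < n; ++j) {
          const double inv_gn = 1.0 / gprop(j);
          for (int i = 0; i < n; ++i) {
            if (i == j) continue;
            const double e0 = Cv(i, j) - D(i, j) / gamma(j);
            const double e1 = Cv(i, j) - D(i, j) * inv_gn;
            const double l1 = log1pexp_c(e1);
            Lnew(i, j) = l1;
            dlp += Y(i, j) * (e1 - e0) - l1 + L(i, j);
          }
        }
      }
      double corr = 0.0;
      for (int j = 0; j < n; ++j) {
        dlp += (alpha(j) - 1.0) * (std::log(gprop(j)) - std::log(gamma(j)));
        // log Dir(gamma | M gprop) - log Dir(gprop | M gamma);
        // the lgamma(M) normalizers cancel
        corr += -std::lgamma(M * gprop(j)) + (M * gprop(j) - 1.0) * std::log(gamma(j))
              + std::lgamma(M * gamma(j)) - (M * gamma(j) - 1.0) * std::log(gprop(j));
      }
      if (monitoring) ++try_g;
      if (std::log(unif_rand()) < dlp + corr) {
        gamma = gprop;
        if (use_lik) L.swap(Lnew);
        if (monitoring) ++acc_g;
      }
    }

    // ---- optional mixture sweep -------------------------------------
    if (mixture) {
      arma::ivec counts(G, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::vec lp(G);
        for (int g = 0; g < G; ++g) {
          double ss = 0.0;
          for (int k = 0; k < d; ++k) {
            double diff = Zt(k, i) - mix_mu(g, k);
            ss += diff * diff;
          }
          lp(g) = std::log(mix_w(g)) - 0.5 * d * std::log(mix_s2(g))
                - ss / (2.0 * mix_s2(g));
        }
        lp -= lp.max();
        arma::vec w = arma::exp(lp);
        w /= arma::accu(w);
        double u = unif_rand(), cum = 0.0;
        int g = G - 1;
        for (int h = 0; h < G; ++h) {
          cum += w(h);
          if (u < cum) { g = h; break; }
        }
        labels(i) = g;
        counts(g) += 1;
      }
      double sw = 0.0;
      for (int g = 0; g < G; ++g) {
        mix_w(g) = R::rgamma(1.0 + counts(g), 1.0);
        sw += mix_w(g);
      }
      mix_w /= sw;
      // conjugate mean/variance updates (empty cluster => prior draw)
      for (int g = 0; g < G; ++g) {
        arma::vec zsum(d, arma::fill::zeros);
        for (int i = 0; i < n; ++i)
          if (labels(i) == g)
            for (int k = 0; k < d; ++k) zsum(k) += Zt(k, i);
        const double prec = counts(g) / mix_s2(g) + 1.0 / mu_prior_var;
        for (int k = 0; k < d; ++k) {
          double m = (zsum(k) / mix_s2(g)) / prec;
          mix_mu(g, k) = m + norm_rand() / std::sqrt(prec);
        }
        double ssr = 0.0;
        for (int i = 0; i < n; ++i)
          if (labels(i) == g)
            for (int k = 0; k < d; ++k) {
              double diff = Zt(k, i) - mix_mu(g, k);
              ssr += diff * diff;
            }
        mix_s2(g) = 1.0 / R::rgamma(s2_prior_a + 0.5 * d * counts(g),
                                    1.0 / (s2_prior_b + 0.5 * ssr));
      }
    }

    // ---- bookkeeping -------------------------------------------------
    if (use_lik) {
      // exp-free: each pair's log-probability is y*eta - L
      double ll = 0.0;
      for (int j = 0; j < n; ++j) {
        const double inv_g = 1.0 / gamma(j);
        for (int i = 0; i < n; ++i) {
          if (i == j) continue;
          if (Y(i, j)) ll += Cv(i, j) - D(i, j) * inv_g;
          ll -= L(i, j);
        }
      }
      ll_trace(t - 1) = ll;
    } else {
      ll_trace(t - 1) = NA_REAL;
    }

    if (adapt && !monitoring && (t % 50 == 0)) {
      if (win_try_z > 0) {
        double r = (double)win_acc_z / win_try_z;
        step_z *= std::exp(0.5 * (r - 0.3));
        step_z = std::min(std::max(step_z, 1e-8), 1e3);
      }
      if (win_try_b > 0) {
        double r = (double)win_acc_b / win_try_b;
        step_b *= std::exp(0.5 * (r - 0.3));
        step_b = std::min(std::max(step_b, 1e-8), 1e3);
      }
      win_acc_z = win_try_z = win_acc_b = win_try_b = 0;
    }

    if (monitoring && thin > 0 && ((t - burn_in) % thin == 0) && keep < n_keep) {
      Z_draws.slice(keep) = Zt.t();
      for (int k = 0; k < p; ++k) {
        beta_draws(keep, k) = beta(k);
        pen_draws(keep, k) = pen(k);
      }
      for (int j = 0; j < n; ++j) gamma_draws(keep, j) = gamma(j);
      sigma2_draws(keep) = sigma2;
      if (mixture) {
        for (int j = 0; j < n; ++j) label_draws(keep, j) = labels(j) + 1;
        for (int g = 0; g < G; ++g) {
          mixw_draws(keep, g) = mix_w(g);
          mixs2_draws(keep, g) = mix_s2(g);
        }
        mixmu_draws.slice(keep) = mix_mu;
      }
      ++keep;
    }

    if (t % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["Z"] = Z_draws, _["beta"] = beta_draws, _["gamma"] = gamma_draws,
    _["sigma2"] = sigma2_draws, _["pen"] = pen_draws,
    _["loglik"] = ll_trace, _["n_kept"] = keep,
    _["labels"] = label_draws, _["mix_w"] = mixw_draws,
    _["mix_mu"] = mixmu_draws, _["mix_s2"] = mixs2_draws,
    _["acc_z"] = try_z > 0 ? (double)acc_z / try_z : NA_REAL,
    _["acc_beta"] = try_b > 0 ? (double)acc_b / try_b : NA_REAL,
    _["acc_gamma"] = try_g > 0 ? (double)acc_g / try_g : NA_REAL,
    _["step_z"] = step_z, _["step_beta"] = step_b,
    _["Z_final"] = Zt.t(), _["gamma_final"] = gamma,
    _["sigma2_final"] = sigma2);
}

// Posterior-mean edge probabilities: Monte-Carlo average of
// plogis(eta_ij) across stored draws (a proper posterior predictive mean,
// not the probability at posterior-mean parameters).
// [[Rcpp::export]]
arma::mat posterior_mean_prob_cpp(const arma::cube& Zd, const arma::mat& betad,
                                  const arma::mat& gammad, const arma::cube& X,
                                  const double beta0) {
  const int n = Zd.n_rows, d = Zd.n_cols, p = betad.n_cols;
  const int S = Zd.n_slices;
  arma::mat P(n, n, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    arma::mat Zt = Zd.slice(s).t();
    arma::mat Cv(n, n);
    Cv.fill(beta0);
    for (int k = 0; k < p; ++k) Cv += betad(s, k) * X.slice(k);
    for (int j = 0; j < n; ++j) {
      const double gj = gammad(s, j);
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        double dd = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = Zt(k, i) - Zt(k, j);
          dd += diff * diff;
        }
        const double eta = Cv(i, j) - std::sqrt(dd) / gj;
        P(i, j) += 1.0 / (1.0 + std::exp(-eta));
      }
    }
  }
  P /= (double)S;
  P.diag().fill(NA_REAL);
  return P;
}
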