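// Gibbs sampler for the generalized multi-environment kernel model with
// disjoint individuals per environment. The genetic covariance is the
// Hadamard product of an environment-level covariance matrix and the full
// record kernel, which breaks inverse-Wishart conjugacy; the environment
// covariance is therefore updated by Metropolis-within-Gibbs random walks
// on log-variances and Fisher-z correlations, with proposal scales adapted
// during burn-in. Latent effects are drawn exactly via the
// residual-decomposition trick. The two dense Cholesky factorizations per
// sweep dominate the cost, so the hot path works on preallocated buffers
// through direct LAPACK calls.
#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#ifdef __unix__
#include <dlfcn.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double JITTER = 1e-8;

// The factorizations here are single-thread-optimal at typical sizes
// (hundreds of records); a multithreaded BLAS oversubscribes the CPU and
// slows the sampler down. Cap OpenBLAS threads if that is the BLAS in use.
static void cap_blas_threads() {
#ifdef __unix__
  typedef void (*setter)(int);
  static bool done = false;
  if (done) return;
  done = true;
  setter f = (setter)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f) f(1);
#endif
}

// In-place lower Cholesky; returns false if not positive definite.
static bool chol_inplace(arma::mat& A) {
  int n = A.n_rows, info = 0;
  F77_CALL(dpotrf)("L", &n, A.memptr(), &n, &info FCONE);
  return info == 0;
}

// Solve L x = b or L' x = b in place (x on entry holds b).
static void trsv(const arma::mat& L, arma::vec& x, bool transpose) {
  int n = L.n_rows, one = 1;
  F77_CALL(dtrsv)("L", transpose ? "T" : "N", "N", &n, L.memptr(), &n,
                  x.memptr(), &one FCONE FCONE FCONE);
}

// x <- L x (lower-triangular multiply in place).
static void trmv(const arma::mat& L, arma::vec& x) {
  int n = L.n_rows, one = 1;
  F77_CALL(dtrmv)("L", "N", "N", &n, L.memptr(), &n, x.memptr(),
                  &one FCONE FCONE FCONE);
}

// y <- A x for symmetric A (lower triangle referenced).
static void symv(const arma::mat& A, const arma::vec& x, arma::vec& y) {
  int n = A.n_rows, one = 1;
  double a = 1.0, b = 0.0;
  F77_CALL(dsymv)("L", &n, &a, A.memptr(), &n, x.memptr(), &one, &b,
                  y.memptr(), &one FCONE);
}

// Environment covariance from theta = (log var_1..m, atanh rho_12, ...).
// Returns false if not positive definite.
static bool make_S(const arma::vec& th, int m, arma::mat& S) {
  S.set_size(m, m);
  for (int j = 0; j < m; ++j) S(j, j) = std::exp(th(j));
  int q = m;
  for (int j = 0; j < m; ++j) {
    for (int k = j + 1; k < m; ++k) {
      double rho = std::tanh(th(q++));
      S(j, k) = S(k, j) = rho * std::sqrt(S(j, j) * S(k, k));
    }
  }
  arma::mat L;
  return arma::chol(L, S, "lower");
}

// log prior of theta: scaled-inv-chi2(df0, S0) on each variance (with the
// log-variance Jacobian) and uniform(-1,1) on each correlation (with the
// Fisher-z Jacobian).
static double log_prior_theta(const arma::vec& th, int m, double df0,
                              const arma::vec& S0) {
  double lp = 0.0;
  for (int j = 0; j < m; ++j) {
    double u = th(j);
    lp += -(df0 / 2.0) * u - df0 * S0(j) / (2.0 * std::exp(u));
  }
  int q = m;
  for (int j = 0; j < m; ++j) {
    for (int k = j + 1; k < m; ++k) {
      double rho = std::tanh(th(q++));
      lp += std::log1p(-rho * rho);
    }
  }
  return lp;
}

// Sigma(i,k) = S(env_i, env_k) * M(i,k) (+ jitter on the diagonal),
// written into a preallocated buffer.
static void hadamard_cov(const arma::mat& S, const arma::mat& M,
                         const arma::ivec& env, arma::mat& Sigma) {
  int n = M.n_rows;
  for (int k = 0; k < n; ++k) {
    int ek = env(k);
    const double* mcol = M.colptr(k);
    double* scol = Sigma.colptr(k);
    for (int i = 0; i < n; ++i) scol[i] = S(env(i), ek) * mcol[i];
    scol[k] += JITTER * S(ek, ek);
  }
}

// -log|L| - 0.5 g' Sigma^-1 g given the lower factor L (uses a scratch
// vector).
static double loglik_chol(const arma::mat& L, const arma::vec& g,
                          arma::vec& scratch) {
  scratch = g;
  trsv(L, scratch, false);
  double ld = 0.0;
  for (arma::uword i = 0; i < L.n_rows; ++i) ld += std::log(L(i, i));
  return -ld - 0.5 * arma::dot(scratch, scratch);
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// [[Rcpp::export]]
List me_general_gibbs(const arma::vec& y, const arma::ivec& env, int m,
                      const arma::mat& K, const arma::mat& B,
                      const arma::ivec& fam, bool background_identity,
                      int iters, int burnin, int thin,
                      double df0, const arma::vec& S0g,
                      const arma::vec& S0b, const arma::vec& S0e,
                      double step_g_init, double step_b_init) {
  cap_blas_threads();
  const int n = y.n_elem;
  const int npair = m * (m - 1) / 2;
  const int ntheta = m + npair;

  arma::vec nj(m, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nj(env(i)) += 1.0;

  // family blocks for the half-sib background
  std::vector<arma::uvec> blocks;
  std::vector<arma::mat> Bsub;
  std::vector<arma::ivec> envsub;
  if (!background_identity) {
    int nf = fam.max() + 1;
    std::vector<std::vector<arma::uword>> tmp(nf);
    for (int i = 0; i < n; ++i) tmp[fam(i)].push_back(i);
    for (int f = 0; f < nf; ++f) {
      arma::uvec ix(tmp[f]);
      blocks.push_back(ix);
      Bsub.push_back(B.submat(ix, ix));
      arma::ivec ef(ix.n_elem);
      for (arma::uword i = 0; i < ix.n_elem; ++i) ef(i) = env(ix(i));
      envsub.push_back(ef);
    }
  }

  // state
  arma::vec mu(m), sige(m), sigb(m);
  for (int j = 0; j < m; ++j) {
    double sy = 0, sy2 = 0;
    for (int i = 0; i < n; ++i) if (env(i) == j) { sy += y(i); sy2 += y(i) * y(i); }
    double mn = sy / nj(j);
    double vr = sy2 / nj(j) - mn * mn;
    mu(j) = mn;
    sige(j) = vr / 3.0;
    sigb(j) = vr / 3.0;
  }
  arma::vec thg(ntheta, arma::fill::zeros);
  for (int j = 0; j < m; ++j) thg(j) = std::log(S0g(j) * 2.0 / 3.0);
  arma::vec thb(ntheta, arma::fill::zeros);
  for (int j = 0; j < m; ++j) thb(j) = std::log(S0b(j) * 2.0 / 3.0);
  arma::vec g(n, arma::fill::zeros), b(n, arma::fill::zeros);

  // preallocated buffers for the dense-covariance work
  arma::mat Sg, Sb, Sigma_g(n, n), Lg(n, n), Sigp(n, n), Lp(n, n), LV(n, n);
  arma::vec scratch(n), de(n), r(n), rhs(n), w(n), u(n), gs(n);
  make_S(thg, m, Sg);
  hadamard_cov(Sg, K, env, Sigma_g);
  Lg = Sigma_g;
  if (!chol_inplace(Lg)) stop("initial genetic covariance not PD");

  make_S(thb, m, Sb);
  std::vector<arma::mat> Lb_blocks(blocks.size());
  if (!background_identity) {
    for (size_t f = 0; f < blocks.size(); ++f) {
      arma::mat Sf;
      Sf.set_size(Bsub[f].n_rows, Bsub[f].n_rows);
      hadamard_cov(Sb, Bsub[f], envsub[f], Sf);
      if (!arma::chol(Lb_blocks[f], Sf, "lower")) stop("initial background covariance not PD");
    }
  }

  double step_g = step_g_init, step_b = step_b_init;
  int acc_g = 0, acc_b = 0, win_g = 0, win_b = 0;
  bool dead_window = false;
  const int WIN = 50;

  const int nd = (iters - burnin) / thin;
  arma::mat mu_dr(nd, m), sige_dr(nd, m);
  arma::mat Sg_dr(nd, m * m), Sb_dr(nd, m * m);
  arma::mat g_dr(n, nd), b_dr(n, nd);
  int s = 0;
  long acc_tot_g = 0, acc_tot_b = 0, n_mh = 0;

  for (int it = 1; it <= iters; ++it) {
    // --- g | theta_g, mu, b, sige : residual-decomposition draw ---------
    for (int i = 0; i < n; ++i) {
      r(i) = y(i) - mu(env(i)) - b(i);
      de(i) = sige(env(i));
    }
    u = rnorm_vec(n);
    trmv(Lg, u);                                     // u ~ N(0, Sigma_g)
    LV = Sigma_g;
    for (int i = 0; i < n; ++i) LV(i, i) += de(i);
    if (!chol_inplace(LV)) stop("marginal covariance not PD at iteration ", it);
    for (int i = 0; i < n; ++i) {
      rhs(i) = r(i) - u(i) - std::sqrt(de(i)) * R::norm_rand();
    }
    w = rhs;
    trsv(LV, w, false);
    trsv(LV, w, true);                               // w = V^-1 rhs
    symv(Sigma_g, w, gs);
    g = u + gs;

    // --- theta_g | g : joint random-walk MH -----------------------------
    {
      double cur = loglik_chol(Lg, g, scratch) +
        log_prior_theta(thg, m, df0, S0g);
      arma::vec thp = thg + step_g * rnorm_vec(ntheta);
      arma::mat Sp;
      bool ok = make_S(thp, m, Sp);
      if (ok) {
        hadamard_cov(Sp, K, env, Sigp);
        Lp = Sigp;
        ok = chol_inplace(Lp);
      }
      if (ok) {
        double prop = loglik_chol(Lp, g, scratch) +
          log_prior_theta(thp, m, df0, S0g);
        if (std::log(R::unif_rand()) < prop - cur) {
          thg = thp; Sg = Sp;
          arma::swap(Sigma_g, Sigp);
          arma::swap(Lg, Lp);
          ++acc_g; ++acc_tot_g;
        }
      }
      ++win_g; ++n_mh;
    }

    // --- b ---------------------------------------------------------------
    if (background_identity) {
      for (int i = 0; i < n; ++i) {
        int j = env(i);
        double v = 1.0 / (1.0 / sigb(j) + 1.0 / sige(j));
        double r2 = y(i) - mu(j) - g(i);
        b(i) = v * r2 / sige(j) + std::sqrt(v) * R::norm_rand();
      }
      // conjugate per-environment background variances
      for (int j = 0; j < m; ++j) {
        double ss = 0;
        for (int i = 0; i < n; ++i) if (env(i) == j) ss += b(i) * b(i);
        sigb(j) = (df0 * S0b(j) + ss) / R::rchisq(df0 + nj(j));
        Sb(j, j) = sigb(j);
      }
    } else {
      for (size_t f = 0; f < blocks.size(); ++f) {
        const arma::uvec& ix = blocks[f];
        int nf = ix.n_elem;
        arma::mat Sf = Lb_blocks[f] * Lb_blocks[f].t();
        arma::vec def(nf), rf(nf);
        for (int i = 0; i < nf; ++i) {
          def(i) = sige(env(ix(i)));
          rf(i) = y(ix(i)) - mu(env(ix(i))) - g(ix(i));
        }
        arma::vec uf = Lb_blocks[f] * rnorm_vec(nf);
        arma::vec dl = arma::sqrt(def) % rnorm_vec(nf);
        arma::mat Vf = Sf;
        Vf.diag() += def;
        arma::vec wf = arma::solve(Vf, rf - uf - dl,
                                   arma::solve_opts::likely_sympd);
        arma::vec bf = uf + Sf * wf;
        for (int i = 0; i < nf; ++i) b(ix(i)) = bf(i);
      }
      // MH on the background covariance parameters
      double cur = log_prior_theta(thb, m, df0, S0b);
      for (size_t f = 0; f < blocks.size(); ++f) {
        arma::vec bf = b(blocks[f]);
        arma::vec sc(bf.n_elem);
        cur += loglik_chol(Lb_blocks[f], bf, sc);
      }
      arma::vec thp = thb + step_b * rnorm_vec(ntheta);
      arma::mat Sp;
      bool ok = make_S(thp, m, Sp);
      std::vector<arma::mat> Lpb(blocks.size());
      double prop = 0.0;
      if (ok) {
        prop = log_prior_theta(thp, m, df0, S0b);
        for (size_t f = 0; f < blocks.size() && ok; ++f) {
          arma::mat Sff;
          Sff.set_size(Bsub[f].n_rows, Bsub[f].n_rows);
          hadamard_cov(Sp, Bsub[f], envsub[f], Sff);
          ok = arma::chol(Lpb[f], Sff, "lower");
          if (ok) {
            arma::vec bf = b(blocks[f]);
            arma::vec sc(bf.n_elem);
            prop += loglik_chol(Lpb[f], bf, sc);
          }
        }
      }
      if (ok && std::log(R::unif_rand()) < prop - cur) {
        thb = thp; Sb = Sp; Lb_blocks = Lpb;
        ++acc_b; ++acc_tot_b;
      }
      ++win_b;
      for (int j = 0; j < m; ++j) sigb(j) = Sb(j, j);
    }

    // --- mu, sige --------------------------------------------------------
    for (int j = 0; j < m; ++j) {
      double sr = 0;
      for (int i = 0; i < n; ++i) if (env(i) == j) sr += y(i) - g(i) - b(i);
      mu(j) = sr / nj(j) + std::sqrt(sige(j) / nj(j)) * R::norm_rand();
    }
    for (int j = 0; j < m; ++j) {
      double ss = 0;
      for (int i = 0; i < n; ++i) {
        if (env(i) == j) {
          double e = y(i) - mu(j) - g(i) - b(i);
          ss += e * e;
        }
      }
      sige(j) = (df0 * S0e(j) + ss) / R::rchisq(df0 + nj(j));
    }
    if (!mu.is_finite() || !sige.is_finite() || !g.is_finite()) {
      stop("divergent chain at iteration ", it);
    }

    // --- adaptation (burn-in only) --------------------------------------
    if (it <= burnin && win_g >= WIN) {
      double rate = (double)acc_g / win_g;
      if (acc_g == 0) dead_window = true;
      if (rate < 0.20) step_g *= 0.8;
      else if (rate > 0.45) step_g *= 1.25;
      acc_g = 0; win_g = 0;
    }
    if (it <= burnin && !background_identity && win_b >= WIN) {
      double rate = (double)acc_b / win_b;
      if (acc_b == 0) dead_window = true;
      if (rate < 0.20) step_b *= 0.8;
      else if (rate > 0.45) step_b *= 1.25;
      acc_b = 0; win_b = 0;
    }

    // --- store -----------------------------------------------------------
    if (it > burnin && (it - burnin) % thin == 0 && s < nd) {
      for (int j = 0; j < m; ++j) { mu_dr(s, j) = mu(j); sige_dr(s, j) = sige(j); }
      for (int j = 0; j < m; ++j) {
        for (int k = 0; k < m; ++k) {
          Sg_dr(s, j * m + k) = Sg(j, k);
          Sb_dr(s, j * m + k) = background_identity
            ? (j == k ? sigb(j) : 0.0) : Sb(j, k);
        }
      }
      g_dr.col(s) = g;
      b_dr.col(s) = b;
      ++s;
    }
  }

  double acc_rate_g = n_mh > 0 ? (double)acc_tot_g / n_mh : NA_REAL;
  double acc_rate_b = (!background_identity && n_mh > 0)
    ? (double)acc_tot_b / n_mh : NA_REAL;

  return List::create(
    _["mu"] = mu_dr, _["sigma2_e"] = sige_dr,
    _["G_env"] = Sg_dr, _["S_b"] = Sb_dr,
    _["g"] = g_dr, _["b"] = b_dr,
    _["accept_g"] = acc_rate_g, _["accept_b"] = acc_rate_b,
    _["step_g"] = step_g, _["step_b"] = step_b,
    _["dead_window"] = dead_window);
}
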