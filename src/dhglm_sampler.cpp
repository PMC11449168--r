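// Blocked MCMC sampler for the trivariate double-hierarchical Gaussian model.
//
// Mean-side blocks (fixed effects, individual and year intercepts) have
// Gaussian full conditionals and are updated by exact Gibbs draws.
// Dispersion-side blocks (fixed effects, individual and year log-SD
// intercepts) and the two 6x6 covariance blocks are updated by
// coordinate-wise adaptive random-walk Metropolis (Roberts-Rosenthal
// diminishing adaptation during warmup, frozen afterwards). Exact Gaussian
// recentering (interweaving) moves between intercepts and their random
// effects remove the additive confounding that slows plain Gibbs mixing.
//
// Correlation matrices are parameterized by canonical partial correlations:
// unconstrained z -> tanh -> Cholesky factor; the prior is LKJ on the
// correlation matrix, so the z-space target includes the transform Jacobian
// (triangular, with an analytic log-determinant).
//
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const int K = 3;    // behaviours
static const int Q = 6;    // random-effect dimension (3 mean + 3 dispersion)
static const int NZ = 15;  // free correlation parameters

// map z (length 15) to tanh'd canonical partial correlations laid out
// row-major over pairs (i, j), i > j
static void z_to_L(const vec& z, mat& L, vec& w) {
  w = arma::tanh(z);
  L.zeros(Q, Q);
  L(0, 0) = 1.0;
  int idx = 0;
  for (int i = 1; i < Q; ++i) {
    double rem = 1.0;
    for (int j = 0; j < i; ++j) {
      L(i, j) = w(idx) * std::sqrt(rem);
      rem *= (1.0 - w(idx) * w(idx));
      ++idx;
    }
    L(i, i) = std::sqrt(std::max(rem, 0.0));
  }
}

// log |d R / d z| for the cpc parameterization (triangular Jacobian)
static double corr_log_jacobian(const vec& z, const mat& L, const vec& w) {
  double lj = 0.0;
  // tanh part
  for (int q = 0; q < NZ; ++q) lj += std::log1p(-w(q) * w(q));
  // w -> R part: for each pair (i > j): log L(j,j) + 0.5 * sum_{k<j} log(1 - w_ik^2)
  int idx = 0;
  for (int i = 1; i < Q; ++i) {
    double cum = 0.0; // sum_{k<j} log(1 - w_ik^2) as j advances
    for (int j = 0; j < i; ++j) {
      if (L(j, j) <= 0.0) return -arma::datum::inf;
      lj += std::log(L(j, j)) + 0.5 * cum;
      cum += std::log1p(-w(idx) * w(idx));
      ++idx;
    }
  }
  return lj;
}

struct LevelState {
  mat w;        // n_groups x 6 random effects (mean | dispersion)
  vec lsd;      // log SDs (6)
  vec z;        // unconstrained correlation parameters (15)
  mat L;        // Cholesky of the correlation matrix
  vec tanh_w;   // tanh(z)
  mat Sigma;    // full covariance
  mat P;        // Sigma^{-1}
  mat M_cond;   // Sigma_ab * Sigma_bb^{-1} (mean | dispersion conditional)
  mat P_cond;   // (Sigma_aa - M Sigma_ba)^{-1}
  mat Md_cond;  // dispersion | mean conditional mean map
  mat Sd_cond;  // dispersion | mean conditional covariance

  void refresh() {
    z_to_L(z, L, tanh_w);
    vec sd = arma::exp(lsd);
    mat R = L * L.t();
    Sigma = arma::diagmat(sd) * R * arma::diagmat(sd);
    P = arma::inv_sympd(arma::symmatu(Sigma));
    mat Saa = Sigma.submat(0, 0, 2, 2), Sab = Sigma.submat(0, 3, 2, 5),
        Sbb = Sigma.submat(3, 3, 5, 5);
    mat Sbb_i = arma::inv_sympd(arma::symmatu(Sbb));
    M_cond = Sab * Sbb_i;
    P_cond = arma::inv_sympd(arma::symmatu(Saa - M_cond * Sab.t()));
    mat Saa_i = arma::inv_sympd(arma::symmatu(Saa));
    Md_cond = Sab.t() * Saa_i;
    Sd_cond = arma::symmatu(Sbb - Md_cond * Sab);
  }

  // joint target of (lsd, z) given the current effects: MVN likelihood of w,
  // half-normal prior on the SDs (+ log-scale Jacobian), LKJ(eta) prior on
  // the correlation matrix (+ cpc-transform Jacobian)
  double block_target(const vec& lsd_p, const vec& z_p, double sd_sd,
                      double lkj_eta) const {
    mat Lp; vec wp;
    z_to_L(z_p, Lp, wp);
    for (int i = 0; i < Q; ++i) {
      if (!(Lp(i, i) > 1e-12)) return -arma::datum::inf;
    }
    vec sd = arma::exp(lsd_p);
    if (!sd.is_finite()) return -arma::datum::inf;
    int n = w.n_rows;
    double sum_log_diag = arma::accu(arma::log(Lp.diag()));
    // quadratic form via triangular solves
    mat Y = (w.each_row() / sd.t()).t();      // 6 x n
    mat Zm = arma::solve(arma::trimatl(Lp), Y);
    double quad = arma::accu(Zm % Zm);
    double ll = -0.5 * n * Q * std::log(2.0 * M_PI) -
                n * (arma::accu(lsd_p) + sum_log_diag) - 0.5 * quad;
    double lp = 0.0;
    for (int m = 0; m < Q; ++m) {
      lp += std::log(2.0) + R::dnorm(sd(m), 0.0, sd_sd, 1) + lsd_p(m);
    }
    lp += (lkj_eta - 1.0) * 2.0 * sum_log_diag;
    double lj = corr_log_jacobian(z_p, Lp, wp);
    return ll + lp + lj;
  }
};

struct Adapt {
  std::vector<double> lscale;
  std::vector<int> acc, tries;
  int batch = 0;
  void init(int n, double s0) {
    lscale.assign(n, std::log(s0));
    acc.assign(n, 0);
    tries.assign(n, 0);
  }
  void maybe_adapt() {
    ++batch;
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
    for (size_t c = 0; c < lscale.size(); ++c) {
      if (tries[c] == 0) continue;
      double rate = (double)acc[c] / tries[c];
      lscale[c] += (rate > 0.44 ? delta : -delta);
      acc[c] = 0;
      tries[c] = 0;
    }
  }
};

// [[Rcpp::export]]
List dhglm_mcmc_cpp(NumericMatrix y_, NumericMatrix X_, IntegerVector id_,
                    IntegerVector year_, int nid, int nyr, List prior,
                    List control, List init) {
  const mat X(X_.begin(), X_.nrow(), X_.ncol());
  const int n = y_.nrow(), p = X_.ncol();
  const double sd_beta = as<double>(prior["sd_beta"]);
  const double sd_gamma = as<double>(prior["sd_gamma"]);
  const double sd_sd = as<double>(prior["sd_sd"]);
  const double lkj_eta = as<double>(prior["lkj_eta"]);
  const int n_iter = as<int>(control["n_iter"]);
  const int n_warmup = as<int>(control["n_warmup"]);
  const int thin = as<int>(control["thin"]);

  mat y(n, K);
  std::vector<std::vector<int>> obs_k(K);
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < n; ++t) {
      double v = y_(t, k);
      y(t, k) = v;
      if (R_finite(v)) obs_k[k].push_back(t);
    }
  }
  std::vector<std::vector<std::vector<int>>> rows_ik(nid,
      std::vector<std::vector<int>>(K));
  std::vector<std::vector<std::vector<int>>> rows_yk(nyr,
      std::vector<std::vector<int>>(K));
  std::vector<std::vector<std::vector<int>>> nzk(K,
      std::vector<std::vector<int>>(p));
  arma::ivec id(n), yr(n);
  for (int t = 0; t < n; ++t) {
    id(t) = id_[t] - 1;
    yr(t) = year_[t] - 1;
  }
  for (int k = 0; k < K; ++k) {
    for (int t : obs_k[k]) {
      rows_ik[id(t)][k].push_back(t);
      rows_yk[yr(t)][k].push_back(t);
      for (int j = 0; j < p; ++j) {
        if (X(t, j) != 0.0) nzk[k][j].push_back(t);
      }
    }
  }
  // individual-constant covariate (total length) for interweaving moves
  const int tl_col = as<int>(control["tl_col"]) - 1;  // 1-based from R, <0 = none
  vec tl_id(std::max(nid, 1));
  bool has_tl_id = tl_col >= 0;
  if (has_tl_id) {
    tl_id.zeros(nid);
    arma::ivec seen(nid, arma::fill::zeros);
    for (int t = 0; t < n; ++t) {
      if (!seen(id_[t] - 1)) {
        tl_id(id_[t] - 1) = X(t, tl_col);
        seen(id_[t] - 1) = 1;
      }
    }
  }

  // observed design submatrices per behaviour (for the beta Gibbs step)
  std::vector<mat> Xk(K);
  for (int k = 0; k < K; ++k) {
    uvec rows(obs_k[k].size());
    for (size_t q = 0; q < obs_k[k].size(); ++q) rows(q) = obs_k[k][q];
    Xk[k] = X.rows(rows);
  }

  // --- state ---------------------------------------------------------------
  mat beta = as<mat>(init["beta"]);    // p x 3
  mat gamma = as<mat>(init["gamma"]);  // p x 3
  LevelState ID, YR;
  ID.w = as<mat>(init["w_id"]);        // nid x 6
  YR.w = as<mat>(init["w_year"]);      // nyr x 6
  ID.lsd = as<vec>(init["lsd_id"]);
  ID.z = as<vec>(init["z_id"]);
  YR.lsd = as<vec>(init["lsd_year"]);
  YR.z = as<vec>(init["z_year"]);
  ID.refresh();
  YR.refresh();

  mat Xbeta = X * beta;    // n x 3
  mat eta(n, K);           // dispersion linear predictor
  mat resid(n, K);         // y - Xbeta - a - u (valid on observed cells)
  auto rebuild_eta = [&]() {
    mat Xg = X * gamma;
    for (int k = 0; k < K; ++k) {
      for (int t = 0; t < n; ++t) {
        eta(t, k) = Xg(t, k) + ID.w(id(t), k + K) + YR.w(yr(t), k + K);
      }
    }
  };
  auto rebuild_resid = [&]() {
    for (int k = 0; k < K; ++k) {
      for (int t : obs_k[k]) {
        resid(t, k) = y(t, k) - Xbeta(t, k) - ID.w(id(t), k) - YR.w(yr(t), k);
      }
    }
  };
  rebuild_eta();
  rebuild_resid();

  // --- adaptation ----------------------------------------------------------
  Adapt ad_gamma, ad_b, ad_v, ad_sig_id, ad_sig_yr;
  ad_gamma.init(K * p, 0.03);
  ad_b.init(nid * K, 0.25);
  ad_v.init(nyr * K, 0.25);
  ad_sig_id.init(Q + NZ, 0.08);
  ad_sig_yr.init(Q + NZ, 0.15);

  // --- output --------------------------------------------------------------
  const int n_fixed = 2 * K * p;          // beta, gamma
  const int n_cov = 2 * (Q + NZ);         // sds + correlations, both levels
  const int n_ranef = Q * (nid + nyr);
  const int npar = n_fixed + n_cov + n_ranef;
  const int n_keep = (n_iter - n_warmup + thin - 1) / thin;
  mat draws(n_keep, npar);
  int keep = 0;

  GetRNGstate();
  for (int iter = 0; iter < n_iter; ++iter) {
    const bool warm = iter < n_warmup;

    // (1) beta_k: Gaussian Gibbs
    for (int k = 0; k < K; ++k) {
      const auto& rows = obs_k[k];
      const int m = rows.size();
      vec wgt(m), ytl(m);
      for (int q = 0; q < m; ++q) {
        int t = rows[q];
        wgt(q) = std::exp(-2.0 * eta(t, k));
        ytl(q) = resid(t, k) + Xbeta(t, k);  // y - a - u
      }
      mat Xw = Xk[k].each_col() % wgt;
      mat A = Xk[k].t() * Xw;
      A.diag() += 1.0 / (sd_beta * sd_beta);
      vec rhs = Xw.t() * ytl;
      mat U = arma::chol(arma::symmatu(A));
      vec mcond = arma::solve(A, rhs);
      vec zr(p);
      for (int j = 0; j < p; ++j) zr(j) = R::norm_rand();
      vec bnew = mcond + arma::solve(arma::trimatu(U), zr);
      beta.col(k) = bnew;
      vec xb = X * bnew;
      for (int t = 0; t < n; ++t) Xbeta(t, k) = xb(t);
      for (int t : rows) {
        resid(t, k) = y(t, k) - Xbeta(t, k) - ID.w(id(t), k) - YR.w(yr(t), k);
      }
    }

    // (2) a_i: Gaussian Gibbs given b_i
    for (int i = 0; i < nid; ++i) {
      vec b_i = ID.w.row(i).subvec(K, Q - 1).t();
      vec m0 = ID.M_cond * b_i;
      mat A = ID.P_cond;
      vec rhs = A * m0;
      for (int k = 0; k < K; ++k) {
        double qk = 0.0, rk = 0.0;
        for (int t : rows_ik[i][k]) {
          double wgt = std::exp(-2.0 * eta(t, k));
          qk += wgt;
          rk += wgt * (resid(t, k) + ID.w(i, k));  // y - Xb - u
        }
        A(k, k) += qk;
        rhs(k) += rk;
      }
      mat U = arma::chol(arma::symmatu(A));
      vec mcond = arma::solve(A, rhs);
      vec zr(K);
      for (int k = 0; k < K; ++k) zr(k) = R::norm_rand();
      vec anew = mcond + arma::solve(arma::trimatu(U), zr);
      for (int k = 0; k < K; ++k) {
        double delta = anew(k) - ID.w(i, k);
        ID.w(i, k) = anew(k);
        for (int t : rows_ik[i][k]) resid(t, k) -= delta;
      }
    }

    // (3) u_y: Gaussian Gibbs given v_y
    for (int g = 0; g < nyr; ++g) {
      vec v_g = YR.w.row(g).subvec(K, Q - 1).t();
      vec m0 = YR.M_cond * v_g;
      mat A = YR.P_cond;
      vec rhs = A * m0;
      for (int k = 0; k < K; ++k) {
        double qk = 0.0, rk = 0.0;
        for (int t : rows_yk[g][k]) {
          double wgt = std::exp(-2.0 * eta(t, k));
          qk += wgt;
          rk += wgt * (resid(t, k) + YR.w(g, k));
        }
        A(k, k) += qk;
        rhs(k) += rk;
      }
      mat U = arma::chol(arma::symmatu(A));
      vec mcond = arma::solve(A, rhs);
      vec zr(K);
      for (int k = 0; k < K; ++k) zr(k) = R::norm_rand();
      vec unew = mcond + arma::solve(arma::trimatu(U), zr);
      for (int k = 0; k < K; ++k) {
        double delta = unew(k) - YR.w(g, k);
        YR.w(g, k) = unew(k);
        for (int t : rows_yk[g][k]) resid(t, k) -= delta;
      }
    }

    // (4) exact interweaving moves between fixed effects and random effects
    // (likelihood-invariant: mu and eta do not change). Shifting a fixed
    // effect whose covariate is constant within groups by delta while
    // subtracting delta * covariate from the group effects leaves the
    // likelihood untouched, and the conditional of delta is Gaussian.
    auto recenter = [&](LevelState& lev, int col, double& coef,
                        double prior_sd, const vec* cvec) {
      int m = lev.w.n_rows;
      double prec = 1.0 / (prior_sd * prior_sd);
      double lin = -coef / (prior_sd * prior_sd);
      for (int g = 0; g < m; ++g) {
        double c_g = cvec ? (*cvec)(g) : 1.0;
        prec += c_g * c_g * lev.P(col, col);
        lin += c_g * arma::dot(lev.P.row(col), lev.w.row(g));
      }
      double delta = lin / prec + R::norm_rand() / std::sqrt(prec);
      coef += delta;
      if (cvec) lev.w.col(col) -= delta * (*cvec);
      else lev.w.col(col) -= delta;
    };
    for (int k = 0; k < K; ++k) {
      recenter(ID, k, beta(0, k), sd_beta, nullptr);
      recenter(YR, k, beta(0, k), sd_beta, nullptr);
      recenter(ID, k + K, gamma(0, k), sd_gamma, nullptr);
      recenter(YR, k + K, gamma(0, k), sd_gamma, nullptr);
      if (has_tl_id) {
        recenter(ID, k, beta(tl_col, k), sd_beta, &tl_id);
        recenter(ID, k + K, gamma(tl_col, k), sd_gamma, &tl_id);
      }
    }

    // (5) gamma: coordinate-wise adaptive MH
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < p; ++j) {
        int c = k * p + j;
        double s = std::exp(ad_gamma.lscale[c]);
        double eps = s * R::norm_rand();
        double dlp = R::dnorm(gamma(j, k) + eps, 0.0, sd_gamma, 1) -
                     R::dnorm(gamma(j, k), 0.0, sd_gamma, 1);
        for (int t : nzk[k][j]) {
          double de = eps * X(t, j);
          double e0 = eta(t, k);
          double r2 = resid(t, k) * resid(t, k);
          dlp += -de - 0.5 * r2 * (std::exp(-2.0 * (e0 + de)) - std::exp(-2.0 * e0));
        }
        ++ad_gamma.tries[c];
        if (std::log(R::unif_rand()) < dlp) {
          ++ad_gamma.acc[c];
          gamma(j, k) += eps;
          for (int t : nzk[k][j]) eta(t, k) += eps * X(t, j);
        }
      }
    }

    // (6,7) dispersion random effects: coordinate-wise adaptive MH with the
    // joint MVN prior entering through the precision matrix
    auto update_disp_ranef = [&](LevelState& lev, Adapt& ad,
                                 std::vector<std::vector<std::vector<int>>>& rows_gk) {
      int m = lev.w.n_rows;
      for (int g = 0; g < m; ++g) {
        for (int k = 0; k < K; ++k) {
          int col = k + K;
          int c = g * K + k;
          double s = std::exp(ad.lscale[c]);
          double eps = s * R::norm_rand();
          double pw = arma::dot(lev.P.row(col), lev.w.row(g));
          double dlp = -(eps * pw + 0.5 * eps * eps * lev.P(col, col));
          for (int t : rows_gk[g][k]) {
            double e0 = eta(t, k);
            double r2 = resid(t, k) * resid(t, k);
            dlp += -eps - 0.5 * r2 * (std::exp(-2.0 * (e0 + eps)) - std::exp(-2.0 * e0));
          }
          ++ad.tries[c];
          if (std::log(R::unif_rand()) < dlp) {
            ++ad.acc[c];
            lev.w(g, col) += eps;
            for (int t : rows_gk[g][k]) eta(t, k) += eps;
          }
        }
      }
    };
    update_disp_ranef(ID, ad_b, rows_ik);
    update_disp_ranef(YR, ad_v, rows_yk);

    // (8,9) covariance blocks: coordinate-wise adaptive MH on
    // (log SDs, unconstrained correlations)
    auto update_cov = [&](LevelState& lev, Adapt& ad) {
      double cur = lev.block_target(lev.lsd, lev.z, sd_sd, lkj_eta);
      for (int c = 0; c < Q + NZ; ++c) {
        double s = std::exp(ad.lscale[c]);
        double eps = s * R::norm_rand();
        vec lsd_p = lev.lsd, z_p = lev.z;
        if (c < Q) lsd_p(c) += eps; else z_p(c - Q) += eps;
        double prop = lev.block_target(lsd_p, z_p, sd_sd, lkj_eta);
        ++ad.tries[c];
        if (std::log(R::unif_rand()) < prop - cur) {
          ++ad.acc[c];
          lev.lsd = lsd_p;
          lev.z = z_p;
          cur = prop;
        }
      }
      lev.refresh();
    };
    update_cov(ID, ad_sig_id);
    update_cov(YR, ad_sig_yr);

    if (warm && (iter + 1) % 50 == 0) {
      ad_gamma.maybe_adapt();
      ad_b.maybe_adapt();
      ad_v.maybe_adapt();
      ad_sig_id.maybe_adapt();
      ad_sig_yr.maybe_adapt();
    }

    // --- store ------------------------------------------------------------
    if (!warm && (iter - n_warmup) % thin == 0) {
      int c = 0;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j) draws(keep, c++) = beta(j, k);
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j) draws(keep, c++) = gamma(j, k);
      auto store_cov = [&](const LevelState& lev) {
        for (int m = 0; m < Q; ++m) draws(keep, c++) = std::exp(lev.lsd(m));
        mat R = lev.L * lev.L.t();
        for (int i = 1; i < Q; ++i)
          for (int j = 0; j < i; ++j) draws(keep, c++) = R(i, j);
      };
      store_cov(ID);
      store_cov(YR);
      for (int m = 0; m < Q; ++m)
        for (int g = 0; g < nid; ++g) draws(keep, c++) = ID.w(g, m);
      for (int m = 0; m < Q; ++m)
        for (int g = 0; g < nyr; ++g) draws(keep, c++) = YR.w(g, m);
      ++keep;
    }
    if ((iter + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  return List::create(_["draws"] = draws);
}
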