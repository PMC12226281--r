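// Coordinate-descent core for the kernel-weighted elastic net and the
// per-path model-selection criteria. Works on the Gram form
//   G = X*'X*,  c = X*'y*
// so that one Gram computation per bandwidth serves the whole
// (pi, lambda) grid (covariance updates).
#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Q = M'M via dsyrk (half the flops of a general gemm), symmetrized.
static mat crossprod_syrk(const mat& M) {
  const int k = (int)M.n_rows, d = (int)M.n_cols;
  mat Q(d, d, fill::zeros);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dsyrk)("U", "T", &d, &k, &one, M.memptr(), &k, &zero,
                  Q.memptr(), &d FCONE FCONE);
  return symmatu(Q);
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One full pass over coordinates; returns max absolute coefficient change.
// Objective: 1/2 b'Gb - c'b + lam * sum_j [ (1-pi)/2 b_j^2 + pi |b_j| ]
// gb = G * beta is maintained incrementally: only changed coordinates pay
// an O(p) update (glmnet-style covariance updates).
static double cd_sweep(const mat& G, const vec& c, double lam, double pi,
                       vec& beta, vec& gb, const uvec& idx) {
  const double l1 = lam * pi, l2 = lam * (1.0 - pi);
  double delta = 0.0;
  for (uword k = 0; k < idx.n_elem; ++k) {
    uword j = idx[k];
    double gjj = G(j, j);
    if (gjj <= 0.0) { beta[j] = 0.0; continue; }
    // partial residual correlation for coordinate j
    double z = c[j] - gb[j] + gjj * beta[j];
    double bnew = soft(z, l1) / (gjj + l2);
    double d = bnew - beta[j];
    if (d != 0.0) {
      gb += d * G.col(j);
      beta[j] = bnew;
      d = std::abs(d);
      if (d > delta) delta = d;
    }
  }
  return delta;
}

// Solve one (lambda, pi) point by coordinate descent with an active-set
// strategy, sweeping only the coordinates in sweep_set; beta is the warm
// start and is overwritten; gb must equal G * beta on entry and is kept in
// sync (over all p coordinates, so KKT checks stay cheap).
static int cd_solve(const mat& G, const vec& c, double lam, double pi,
                    vec& beta, vec& gb, const uvec& sweep_set,
                    double tol, int maxit) {
  int it = 0;
  while (it < maxit) {
    double delta = cd_sweep(G, c, lam, pi, beta, gb, sweep_set);
    ++it;
    if (delta < tol) return it;
    // iterate on the current active set until stable, then re-check all
    uvec act = find(beta != 0.0);
    while (it < maxit && act.n_elem > 0) {
      double d2 = cd_sweep(G, c, lam, pi, beta, gb, act);
      ++it;
      if (d2 < tol) break;
    }
  }
  return -1; // not converged
}

// Solve a descending lambda path with warm starts and sequential
// strong-rule screening (coordinates with small gradient are excluded from
// the sweeps, then checked against the KKT conditions and re-included if
// violated). beta/gb carry the warm start across calls.
static bool enet_path_core(const mat& G, const vec& c, const vec& lambdas,
                           double pi, vec& beta, vec& gb, mat* Beta,
                           double tol, int maxit, ivec* iters) {
  const uword p = G.n_rows, L = lambdas.n_elem;
  bool ok = true;
  double lam_prev = lambdas.n_elem ? lambdas[0] : 0.0;
  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double thr = pi * (2.0 * lam - lam_prev);
    uvec screened = find((abs(c - gb) >= thr) || (beta != 0.0));
    int it = 0;
    for (;;) {
      int r = cd_solve(G, c, lam, pi, beta, gb, screened, tol, maxit);
      if (r < 0) { it = -1; ok = false; break; }
      it += r;
      // KKT check on the screened-out coordinates
      vec g = abs(c - gb);
      uvec in(p, fill::zeros);
      in.elem(screened).ones();
      double cut = lam * pi * (1.0 + 1e-12) + 1e-12;
      std::vector<uword> v;
      for (uword j = 0; j < p; ++j)
        if (!in[j] && g[j] > cut) v.push_back(j);
      if (v.empty()) break;
      screened = join_cols(screened, uvec(v));
    }
    if (iters) (*iters)[l] = it;
    if (Beta) Beta->col(l) = beta;
    lam_prev = lam;
  }
  return ok;
}

// cd_solve over a restricted coordinate set: wraps the full-G solver by
// sweeping only idx in the outer loop. (Defined after cd_solve above.)
// [[Rcpp::export]]
Rcpp::List cpp_enet_path(const arma::mat& G, const arma::vec& c,
                         const arma::vec& lambdas, double pi,
                         double tol, int maxit,
                         Rcpp::Nullable<Rcpp::NumericVector> beta_init = R_NilValue) {
  const uword p = G.n_rows, L = lambdas.n_elem;
  mat Beta(p, L, fill::zeros);
  vec beta(p, fill::zeros);
  if (beta_init.isNotNull())
    beta = Rcpp::as<vec>(beta_init.get());
  vec gb = G * beta;
  ivec iters(L);
  bool ok = enet_path_core(G, c, lambdas, pi, beta, gb, &Beta, tol, maxit,
                           &iters);
  return Rcpp::List::create(Rcpp::Named("beta") = Beta,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = ok);
}

// Per-lambda fit summaries and the GIC bias term for a whole path.
// Xs, ys: weighted (starred) design; w: normalized kernel weights (sum n').
// Returns df, sigma2, loglik, gic_bias (NaN rows where the fit is degenerate).
// [[Rcpp::export]]
Rcpp::List cpp_path_criteria(const arma::mat& Xs, const arma::vec& ys,
                             const arma::vec& w, const arma::mat& G,
                             const arma::mat& Beta,
                             const arma::vec& lambdas, double pi,
                             double jitter, bool want_bias, bool mle_sigma,
                             bool homo_ll, bool scale_penalty,
                             double bias_threshold) {
  const uword n = Xs.n_rows, L = Beta.n_cols;
  const double logw_sum = accu(log(w));
  const double c2pi = std::log(2.0 * M_PI);
  vec df(L), sigma2(L), loglik(L), bias(L), rssv(L);
  df.fill(datum::nan); sigma2.fill(datum::nan);
  loglik.fill(datum::nan); bias.fill(datum::nan); rssv.fill(datum::nan);
  for (uword l = 0; l < L; ++l) {
    vec bl = Beta.col(l);
    uvec A = find(bl != 0.0);
    double d = (double)A.n_elem;
    df[l] = d;
    vec resid = A.n_elem ? vec(ys - Xs.cols(A) * bl.elem(A)) : ys;
    double rss = dot(resid, resid);
    rssv[l] = rss;
    double rdf = (double)n - d;
    if (rdf < 1.0) continue;                 // no residual dof
    double s2 = mle_sigma ? rss / (double)n : rss / rdf;
    if (!(s2 > 0.0)) continue;               // perfect interpolation
    sigma2[l] = s2;
    // Gaussian log-likelihood on the starred scale; per-sample variance
    // w_i * s2 (hetero) or s2 (homo)
    vec vs = w * s2;
    if (homo_ll)
      loglik[l] = -0.5 * ((double)n * (c2pi + std::log(s2)) + rss / s2);
    else
      loglik[l] = -0.5 * ((double)n * c2pi + logw_sum
                          + (double)n * std::log(s2)
                          + accu(square(resid) / vs));
    if (!want_bias) continue;
    if (A.n_elem == 0) { bias[l] = 0.0; continue; }
    // -2*loglik alone already far above the incumbent criterion value:
    // the bias correction (empirically non-negative) cannot rescue it
    if (-2.0 * loglik[l] > bias_threshold) continue;
    // GIC bias tr(Rhat^-1 Qhat) restricted to the active set
    vec lam_d = resid / vs;                  // Lambda-hat diagonal
    mat XA = Xs.cols(A);
    vec betaA = bl.elem(A);
    vec sl = lambdas[l] * ((1.0 - pi) + pi / abs(betaA));  // Sigma_lambda diag
    if (scale_penalty) sl /= (double)n;
    mat Rhat = G.submat(A, A) / (double)n;
    Rhat.diag() += sl;
    mat M = XA.each_col() % lam_d;           // Lambda * XA
    mat Q = crossprod_syrk(M);               // XA' Lambda^2 XA
    vec v = XA.t() * lam_d;                  // (1' Lambda XA)'
    Q -= (sl % betaA) * v.t();
    Q /= (double)n;
    mat S;
    if (!solve(S, Rhat, Q, solve_opts::likely_sympd + solve_opts::no_approx)) {
      Rhat.diag() += jitter;
      if (!solve(S, Rhat, Q, solve_opts::likely_sympd + solve_opts::no_approx))
        continue;
    }
    bias[l] = trace(S);
  }
  return Rcpp::List::create(Rcpp::Named("df") = df,
                            Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("rss") = rssv,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("gic_bias") = bias);
}

// k-fold CV error along a lambda path at fixed pi, on the weighted design.
// foldid: 1..k per retained sample. Error per fold is
//   sum_test w_i (y_i - r_i'b)^2 / sum_test w_i  (starred residuals / sum w),
// averaged over folds.
// [[Rcpp::export]]
arma::vec cpp_cv_error(const arma::mat& Xs, const arma::vec& ys,
                       const arma::vec& w, const arma::mat& G,
                       const arma::vec& c, const arma::ivec& foldid, int k,
                       const arma::vec& lambdas, double pi,
                       double tol, int maxit) {
  const uword L = lambdas.n_elem, p = Xs.n_cols;
  vec err(L, fill::zeros);
  for (int f = 1; f <= k; ++f) {
    uvec test = find(foldid == f);
    if (test.n_elem == 0) Rcpp::stop("empty cross-validation fold");
    mat Xt = Xs.rows(test);
    vec yt = ys.elem(test);
    mat Gtr = G - Xt.t() * Xt;
    vec ctr = c - Xt.t() * yt;
    double wsum = accu(w.elem(test));
    vec beta(p, fill::zeros);
    vec gb(p, fill::zeros);
    mat Btr(p, L);
    enet_path_core(Gtr, ctr, lambdas, pi, beta, gb, &Btr, tol, maxit,
                   nullptr);
    mat Rres = repmat(yt, 1, L) - Xt * Btr;
    err += sum(square(Rres), 0).t() / wsum;
  }
  return err / (double)k;
}
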