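// ADMM window solver, NNLS, and batch drivers for SL-PRU.
//
// All matrices here are tiny (C <= ~32 channels, R <= ~13 endmembers,
// N = 9 pixels per 3x3 window) but the unmixer and the simulation study
// solve tens of thousands of windows, hence compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise prox of z - y*log(z) under (rho/2)(z - v)^2:
//   rho z^2 + (1 - rho v) z - y = 0, positive root.
// For y = 0 this reduces to max(v - 1/rho, 0).
static mat prox_pois_c(const mat& V, const mat& Y, double rho) {
  mat t = V - 1.0 / rho;
  return 0.5 * (t + sqrt(square(t) + (4.0 / rho) * Y));
}

// Weighted singular value thresholding. Exact prox when tau*wp is
// non-decreasing along descending singular values.
static mat prox_wnn_c(const mat& V, const vec& wp, double tau) {
  mat U, W;
  vec s;
  svd_econ(U, s, W, V);
  vec sh = s - tau * wp.head(s.n_elem);
  sh.transform([](double x) { return x > 0.0 ? x : 0.0; });
  return U * diagmat(sh) * W.t();
}

// Row-wise group soft thresholding with per-row weights.
static mat prox_l21_c(const mat& V, const vec& wq, double tau) {
  mat Z = V;
  for (uword r = 0; r < V.n_rows; ++r) {
    double nr = norm(V.row(r), 2);
    double th = tau * wq(r);
    if (nr <= th)
      Z.row(r).zeros();
    else
      Z.row(r) *= (1.0 - th / nr);
  }
  return Z;
}

// Lawson-Hanson active set NNLS: argmin_{x >= 0} ||M x - y||_2.
static vec nnls_c(const mat& M, const vec& y) {
  const uword n = M.n_cols;
  vec x(n, fill::zeros);
  uvec passive(n, fill::zeros);
  vec w = M.t() * (y - M * x);
  double wtol = 1e-10 * std::max(1.0, norm(M.t() * y, "inf"));
  const uword maxit = 30 * n + 30;
  uword iter = 0;
  while (true) {
    int t = -1;
    double wmax = wtol;
    for (uword j = 0; j < n; ++j)
      if (!passive(j) && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    passive((uword)t) = 1;
    while (true) {
      uvec P = find(passive == 1);
      vec z;
      if (!solve(z, M.cols(P), y)) { z = pinv(M.cols(P)) * y; }
      if (z.n_elem > 0 && z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      double alpha = datum::inf;
      vec xp = x(P);
      for (uword k = 0; k < P.n_elem; ++k)
        if (z(k) <= 0 && xp(k) - z(k) > 0)
          alpha = std::min(alpha, xp(k) / (xp(k) - z(k)));
      if (!std::isfinite(alpha)) alpha = 0.0;
      x(P) = xp + alpha * (z - xp);
      for (uword k = 0; k < P.n_elem; ++k)
        if (x(P(k)) <= 1e-12) { passive(P(k)) = 0; x(P(k)) = 0.0; }
      if (++iter > maxit) {
        x.transform([](double v) { return v > 0.0 ? v : 0.0; });
        return x;
      }
    }
    w = M.t() * (y - M * x);
    if (++iter > maxit) break;
  }
  return x;
}

struct AdmmOut {
  mat A;
  uword iters;
  double pri, dua;
  bool conv;
};

// Four-block consensus ADMM (scaled duals) for
//   min_{A>=0} loss(MA; Y) + l1 ||A||_{wp,*} + l2 ||Wq A||_{2,1}
// with splits Z = MA (loss prox), U = A (nuclear), V = A (l21), W = A (>= 0).
// A-update: (M'M + 3I) A = M'(Z - Gz) + (U - Gu) + (V - Gv) + (W - Gw).
// Stopping: Boyd et al. relative + absolute criterion, eps_abs = eps_rel = tol.
static AdmmOut admm_core(const mat& Y, const mat& M, double l1, double l2,
                         const vec& wp, const vec& wq, double mu, double tol,
                         uword max_iter, bool poisson, const mat& A0) {
  const uword C = Y.n_rows, N = Y.n_cols, R = M.n_cols;
  const mat Mt = M.t();
  const mat Kinv = inv_sympd(Mt * M + 3.0 * eye(R, R));
  mat A = A0;
  mat MA = M * A;
  mat Z = MA, U = A, V = A, W = clamp(A, 0.0, datum::inf);
  mat Gz(C, N, fill::zeros), Gu(R, N, fill::zeros), Gv(R, N, fill::zeros),
      Gw(R, N, fill::zeros);
  mat Zo, Uo, Vo, Wo, rhs;
  AdmmOut out;
  out.pri = datum::inf;
  out.dua = datum::inf;
  out.conv = false;
  out.iters = 0;
  const double sq_pri = std::sqrt((double)(C * N + 3 * R * N));
  const double sq_dua = std::sqrt((double)(R * N));
  const uword check_every = 5;
  for (uword it = 1; it <= max_iter; ++it) {
    out.iters = it;
    rhs = Mt * (Z - Gz);
    rhs += U - Gu;
    rhs += V - Gv;
    rhs += W - Gw;
    A = Kinv * rhs;
    MA = M * A;
    bool check = (it % check_every == 0) || it == max_iter;
    if (check) { Zo = Z; Uo = U; Vo = V; Wo = W; }
    if (poisson)
      Z = prox_pois_c(MA + Gz, Y, mu);
    else
      Z = (Y + mu * (MA + Gz)) / (1.0 + mu);
    U = (l1 > 0) ? prox_wnn_c(A + Gu, wp, l1 / mu) : (A + Gu);
    V = (l2 > 0) ? prox_l21_c(A + Gv, wq, l2 / mu) : (A + Gv);
    W = clamp(A + Gw, 0.0, datum::inf);
    Gz += MA - Z;
    Gu += A - U;
    Gv += A - V;
    Gw += A - W;
    if (!check) continue;
    if (!A.is_finite())
      Rcpp::stop("ADMM diverged (non-finite iterate) at iteration %d", (int)it);
    double rz = norm(MA - Z, "fro"), ru = norm(A - U, "fro"),
           rv = norm(A - V, "fro"), rw = norm(A - W, "fro");
    out.pri = std::sqrt(rz * rz + ru * ru + rv * rv + rw * rw);
    mat S = Mt * (Z - Zo) + (U - Uo) + (V - Vo) + (W - Wo);
    out.dua = mu * norm(S, "fro");
    double nA = norm(A, "fro");
    double nAx = std::sqrt(std::pow(norm(MA, "fro"), 2) + 3.0 * nA * nA);
    double nB = std::sqrt(std::pow(norm(Z, "fro"), 2) +
                          std::pow(norm(U, "fro"), 2) +
                          std::pow(norm(V, "fro"), 2) +
                          std::pow(norm(W, "fro"), 2));
    mat Gs = Mt * Gz + Gu + Gv + Gw;
    double eps_pri = sq_pri * tol + tol * std::max(nAx, nB);
    double eps_dua = sq_dua * tol + tol * mu * norm(Gs, "fro");
    if (out.pri <= eps_pri && out.dua <= eps_dua) {
      out.conv = true;
      break;
    }
  }
  out.A = clamp(A, 0.0, datum::inf);
  return out;
}

// Inverse-magnitude reweighting from a previous solution.
static void reweight(const mat& A, double eps_scale, vec& wp, vec& wq) {
  vec s = svd(A);
  double ep = eps_scale * std::max(s.max(), 1.0);
  wp = 1.0 / (s.head(wp.n_elem) + ep);
  vec rn(A.n_rows);
  for (uword r = 0; r < A.n_rows; ++r) rn(r) = norm(A.row(r), 2);
  double eq = std::max(eps_scale * rn.max(), eps_scale);
  wq = 1.0 / (rn + eq);
}

static AdmmOut solve_window_c(const mat& Y, const mat& M, double l1, double l2,
                              double mu, double tol, int max_iter, int outer,
                              double eps_scale, bool poisson, bool weighted,
                              const vec& wp_fixed, const vec& wq_fixed,
                              vec& wp_out, vec& wq_out) {
  const uword R = M.n_cols, N = Y.n_cols;
  mat A0(R, N);
  for (uword j = 0; j < N; ++j) A0.col(j) = nnls_c(M, Y.col(j));
  vec wp(std::min(R, N), fill::ones), wq(R, fill::ones);
  const bool fixed = wp_fixed.n_elem > 0 || wq_fixed.n_elem > 0;
  if (fixed) {
    if (wp_fixed.n_elem > 0) wp = wp_fixed.head(wp.n_elem);
    if (wq_fixed.n_elem > 0) wq = wq_fixed.head(R);
  }
  int passes = (weighted && !fixed) ? outer : 1;
  if (passes < 1) passes = 1;
  // Adaptive weighted solves derive the first weights from the NNLS warm
  // start so the inverse-magnitude weights are scale-matched to the data
  // from the outset; later passes reweight from the previous solution.
  if (weighted && !fixed && accu(A0) > 0) reweight(A0, eps_scale, wp, wq);
  AdmmOut out;
  for (int p = 0; p < passes; ++p) {
    if (p > 0) {
      if (accu(out.A) > 0) reweight(out.A, eps_scale, wp, wq);
      A0 = out.A;
    }
    out = admm_core(Y, M, l1, l2, wp, wq, mu, tol, (uword)max_iter, poisson, A0);
  }
  wp_out = wp;
  wq_out = wq;
  return out;
}

// [[Rcpp::export]]
Rcpp::List admm_window_cpp(const arma::mat& Y, const arma::mat& M,
                           double lambda1, double lambda2, double mu,
                           double tol, int max_iter, int outer,
                           double eps_scale, bool poisson, bool weighted,
                           const arma::vec& wp_fixed, const arma::vec& wq_fixed) {
  vec wp, wq;
  AdmmOut out = solve_window_c(Y, M, lambda1, lambda2, mu, tol, max_iter,
                               outer, eps_scale, poisson, weighted,
                               wp_fixed, wq_fixed, wp, wq);
  return Rcpp::List::create(
      Rcpp::Named("A") = out.A, Rcpp::Named("iterations") = (int)out.iters,
      Rcpp::Named("primal_residual") = out.pri,
      Rcpp::Named("dual_residual") = out.dua,
      Rcpp::Named("converged") = out.conv, Rcpp::Named("wp") = wp,
      Rcpp::Named("wq") = wq);
}

// Solve a stack of windows; returns an R x N x P cube of abundances.
// [[Rcpp::export]]
arma::cube solve_windows_cpp(const arma::cube& Yw, const arma::mat& M,
                             double lambda1, double lambda2, double mu,
                             double tol, int max_iter, int outer,
                             double eps_scale, bool poisson, bool weighted) {
  const uword P = Yw.n_slices, R = M.n_cols, N = Yw.n_cols;
  cube out(R, N, P);
  vec wp, wq;
  const vec none;
  for (uword p = 0; p < P; ++p) {
    AdmmOut o = solve_window_c(Yw.slice(p), M, lambda1, lambda2, mu, tol,
                               max_iter, outer, eps_scale, poisson, weighted,
                               none, none, wp, wq);
    out.slice(p) = o.A;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
arma::vec nnls_cpp(const arma::mat& M, const arma::vec& y) {
  return nnls_c(M, y);
}

// Column-wise NNLS: argmin_{A >= 0} ||Y - MA||_F columnwise.
// [[Rcpp::export]]
arma::mat nnls_cols_cpp(const arma::mat& Y, const arma::mat& M) {
  mat A(M.n_cols, Y.n_cols);
  for (uword j = 0; j < Y.n_cols; ++j) {
    A.col(j) = nnls_c(M, Y.col(j));
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return A;
}
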