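// Elastic-net coordinate descent core and bootstrap driver.
//
// Objective (intercept unpenalized, minimized over beta for centered data):
//   (1/(2n)) * sum_i (y_i - x_i' beta)^2
//     + lambda * [ (1 - alpha)/2 * sum_j beta_j^2 + alpha * sum_j |beta_j| ]
// Cyclic coordinate descent with covariance updates and warm starts along a
// decreasing lambda path; convergence when the largest absolute coefficient
// change in a full sweep drops below `tol` (default 1e-7), capped at
// `max_sweeps` sweeps per lambda value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Column standardization in place: mean 0, sample SD 1 (n-1 denominator).
// Columns with SD below `eps` are zeroed out and flagged (degenerate).
static uvec standardize_inplace(mat& X, double eps = 1e-10) {
  const uword n = X.n_rows, p = X.n_cols;
  uvec degenerate(p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double m = mean(X.col(j));
    X.col(j) -= m;
    double s = (n > 1) ? std::sqrt(dot(X.col(j), X.col(j)) / (double)(n - 1))
                       : 0.0;
    if (s < eps) {
      X.col(j).zeros();
      degenerate(j) = 1;
    } else {
      X.col(j) /= s;
    }
  }
  return degenerate;
}

// Core path solver on pre-centered data. XtX and Xty are Gram quantities of
// the (already centered/standardized) design; diag_n = diag(XtX)/n.
// beta0 is the warm-start vector; the solution for each lambda is written
// into the corresponding column of `out`.
static void cd_path_core(const mat& XtX, const vec& Xty, uword n,
                         double alpha, const vec& lambda, mat& out,
                         double tol, int max_sweeps) {
  const uword p = Xty.n_elem, L = lambda.n_elem;
  const double dn = (double)n;
  vec beta = out.col(0); // warm start: caller seeds column 0
  vec s = XtX * beta;    // s = XtX * beta, maintained incrementally
  vec diag_n = XtX.diag() / dn;
  std::vector<uword> active;
  active.reserve(p);

  // one coordinate-descent sweep over the index set `idxs`; also lower-bounds
  // the objective decrease achieved by the sweep (0.5*(d_j+lridge)*delta_j^2
  // per coordinate update), used to detect stalls on singular resamples
  double sweep_decrease = 0.0;
  auto sweep_over = [&](const std::vector<uword>& idxs, double lridge,
                        double lsoft) -> double {
    double maxdelta = 0.0;
    sweep_decrease = 0.0;
    for (uword j : idxs) {
      const double bj = beta(j);
      const double dj = diag_n(j);
      if (dj <= 0.0) { // degenerate (zeroed) column stays at 0
        if (bj != 0.0) { s -= XtX.col(j) * bj; beta(j) = 0.0; }
        continue;
      }
      const double rho = (Xty(j) - s(j)) / dn + dj * bj;
      const double bnew = soft_threshold(rho, lsoft) / (dj + lridge);
      if (bnew != bj) {
        s += XtX.col(j) * (bnew - bj);
        beta(j) = bnew;
        const double d = std::fabs(bnew - bj);
        if (d > maxdelta) maxdelta = d;
        sweep_decrease += 0.5 * (dj + lridge) * d * d;
      }
    }
    return maxdelta;
  };

  std::vector<uword> all(p);
  for (uword j = 0; j < p; ++j) all[j] = j;

  // Exact-solve acceleration: with the active set A and signs fixed, the
  // minimizer solves (XtX_AA + n*lam*(1-alpha) I) b_A = Xty_A - n*lam*alpha*sgn_A.
  // Accept only if the solved signs match and the KKT conditions hold for the
  // inactive coordinates. Returns true on success (beta and s updated).
  // When every usable column is active (dense bottom of the path) the solve
  // reuses a cached eigendecomposition of XtX, so each lambda costs two
  // small matrix-vector products instead of a fresh factorization.
  bool eig_ready = false;
  mat eigV;
  vec eigval;

  // Accept or partially accept a candidate minimizer `bcand` computed for
  // the current active set and signs. If a sign would flip, step along the
  // segment from beta to bcand up to the first sign crossing (the objective
  // decreases monotonically along that segment), drop the crossing
  // coordinate, and report non-convergence so the caller refines further.
  // On a full step, verify the inactive-coordinate KKT conditions.
  auto finish_candidate = [&](const vec& bcand, double lsoft) -> bool {
    double t = 1.0;
    sword cross = -1;
    if (lsoft > 0.0) {
      for (uword j = 0; j < p; ++j) {
        if (beta(j) != 0.0 && bcand(j) * beta(j) <= 0.0) {
          double tj = beta(j) / (beta(j) - bcand(j));
          if (tj < t) { t = tj; cross = (sword)j; }
        }
      }
    }
    if (t < 1.0) {
      for (uword j = 0; j < p; ++j)
        if (beta(j) != 0.0) beta(j) += t * (bcand(j) - beta(j));
      if (cross >= 0) beta((uword)cross) = 0.0;
      s = XtX * beta;
      return false;
    }
    vec snew = XtX * bcand;
    bool ok = true;
    for (uword j = 0; j < p; ++j) {
      if (bcand(j) != 0.0 || diag_n(j) <= 0.0) continue;
      if (std::fabs(Xty(j) - snew(j)) / dn > lsoft * (1.0 + 1e-12)) {
        ok = false; // KKT violator: the next sweep pulls it into the model
        break;
      }
    }
    beta = bcand; // restricted minimizer: objective never increases
    s = snew;
    return ok;
  };

  auto try_dense = [&](double lridge, double lsoft) -> bool {
    if (!eig_ready) { eig_sym(eigval, eigV, XtX); eig_ready = true; }
    vec denom = eigval + dn * lridge;
    if (denom.min() < 1e-10 * std::max(1.0, eigval.max())) return false;
    vec rhs = Xty;
    if (lsoft > 0.0)
      for (uword j = 0; j < p; ++j)
        if (beta(j) != 0.0)
          rhs(j) -= dn * lsoft * ((beta(j) > 0.0) ? 1.0 : -1.0);
    vec z = (eigV.t() * rhs) / denom;
    vec b = eigV * z;
    for (uword j = 0; j < p; ++j)
      if (diag_n(j) <= 0.0) b(j) = 0.0;
    return finish_candidate(b, lsoft);
  };
  mat cholbuf(p, p);          // preallocated scratch: lower Cholesky factor
  vec rhsbuf(p), candbuf(p);  // of the active-set system, its rhs, candidate
  auto try_exact = [&](double lam, double lridge, double lsoft,
                       bool allow_pinv) -> bool {
    active.clear();
    for (uword j = 0; j < p; ++j)
      if (beta(j) != 0.0 && diag_n(j) > 0.0) active.push_back(j);
    const uword pa = active.size();
    uword usable = 0;
    for (uword j = 0; j < p; ++j) if (diag_n(j) > 0.0) ++usable;
    if (pa == usable && pa > 0) return try_dense(lridge, lsoft);
    if (pa == 0) { // the zero vector is optimal iff KKT holds at 0
      if (lsoft <= 0.0) return false;
      for (uword j = 0; j < p; ++j)
        if (diag_n(j) > 0.0 &&
            std::fabs(Xty(j)) / dn > lsoft * (1.0 + 1e-12)) return false;
      s.zeros();
      return true;
    }
    // in-place Cholesky of XtX_AA + n*lridge*I (no allocations)
    bool chol_ok = true;
    for (uword c = 0; c < pa && chol_ok; ++c) {
      for (uword r = c; r < pa; ++r) {
        double v = XtX(active[r], active[c]);
        if (r == c) v += dn * lridge;
        for (uword k = 0; k < c; ++k) v -= cholbuf(r, k) * cholbuf(c, k);
        if (r == c) {
          if (v <= 1e-12) { chol_ok = false; break; } // singular system
          cholbuf(c, c) = std::sqrt(v);
        } else {
          cholbuf(r, c) = v / cholbuf(c, c);
        }
      }
    }
    for (uword a = 0; a < pa; ++a) {
      double v = Xty(active[a]);
      if (lsoft > 0.0) v -= dn * lsoft * ((beta(active[a]) > 0.0) ? 1.0 : -1.0);
      rhsbuf(a) = v;
    }
    if (chol_ok) {
      // forward then backward substitution, solution left in rhsbuf
      for (uword a = 0; a < pa; ++a) {
        double v = rhsbuf(a);
        for (uword k = 0; k < a; ++k) v -= cholbuf(a, k) * rhsbuf(k);
        rhsbuf(a) = v / cholbuf(a, a);
      }
      for (uword a = pa; a-- > 0; ) {
        double v = rhsbuf(a);
        for (uword k = a + 1; k < pa; ++k) v -= cholbuf(k, a) * rhsbuf(k);
        rhsbuf(a) = v / cholbuf(a, a);
      }
    } else if (!allow_pinv) {
      return false; // singular system: only attempt the SVD route sparingly
    } else {
      // rank-deficient active set (common in near-square bootstrap
      // resamples with lasso): take the minimum-norm stationary point,
      // provided the system is consistent; any sign-consistent solution of
      // the stationarity equations is a global minimizer of the convex
      // objective, and downstream rules only use the zero pattern
      uvec A(active);
      mat M = XtX.submat(A, A);
      M.diag() += dn * lridge;
      vec r = rhsbuf.head(pa);
      vec bA = pinv(M) * r;
      if (norm(M * bA - r, "inf") > 1e-8 * std::max(1.0, norm(r, "inf")))
        return false; // inconsistent: this pattern is not optimal
      rhsbuf.head(pa) = bA;
    }
    candbuf.zeros();
    for (uword a = 0; a < pa; ++a) candbuf(active[a]) = rhsbuf(a);
    return finish_candidate(candbuf, lsoft);
  };

  for (uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    const double lridge = lam * (1.0 - alpha);
    const double lsoft = lam * alpha;
    // the warm-started nonzero pattern is usually already correct, so the
    // exact solve is attempted before any sweep; coordinate descent repairs
    // the pattern whenever the solve is rejected (sign flip / KKT violation).
    // A sweep whose guaranteed objective decrease falls below ~tol^2 has
    // stalled on a (numerically) flat face and is accepted as converged.
    const double stall = 0.1 * tol * tol;
    int sweeps = 0;
    while (sweeps < max_sweeps) {
      if (try_exact(lam, lridge, lsoft, sweeps % 8 == 0)) break;
      double d_full = sweep_over(all, lridge, lsoft);
      ++sweeps;
      if (d_full < tol || sweep_decrease < stall) break;
    }
    out.col(l) = beta;
  }
}

// [[Rcpp::export]]
arma::mat cpp_enet_path(const arma::mat& X, const arma::vec& y, double alpha,
                        const arma::vec& lambda, double tol = 1e-7,
                        int max_sweeps = 100000) {
  const uword n = X.n_rows, p = X.n_cols;
  vec xm = mean(X, 0).t();
  mat Xc = X.each_row() - xm.t();
  vec yc = y - mean(y);
  mat XtX = Xc.t() * Xc;
  vec Xty = Xc.t() * yc;
  mat out(p, lambda.n_elem, fill::zeros);
  cd_path_core(XtX, Xty, n, alpha, lambda, out, tol, max_sweeps);
  return out;
}

// Minimum-norm least squares via pseudo-inverse (rank-revealing SVD).
// [[Rcpp::export]]
arma::vec cpp_ols_minnorm(const arma::mat& X, const arma::vec& y) {
  vec xm = mean(X, 0).t();
  mat Xc = X.each_row() - xm.t();
  vec yc = y - mean(y);
  return pinv(Xc) * yc;
}

// k-fold CV mean squared prediction error along a fixed lambda path.
// foldid: 1-based fold labels, length n. Training folds are re-standardized
// (mean 0 / SD 1 from training rows only) and the held-out rows are mapped
// through the training transform; predictions are on the original y scale.
// Returns a k x L matrix of per-fold held-out MSEs.
// [[Rcpp::export]]
arma::mat cpp_cv_mse(const arma::mat& X, const arma::vec& y, double alpha,
                     const arma::vec& lambda, const arma::ivec& foldid,
                     double tol = 1e-7, int max_sweeps = 100000) {
  const uword n = X.n_rows, p = X.n_cols, L = lambda.n_elem;
  const int k = foldid.max();
  mat mse(k, L, fill::zeros);

  for (int f = 1; f <= k; ++f) {
    uvec test = find(foldid == f);
    uvec train = find(foldid != f);
    mat Xtr = X.rows(train);
    vec ytr = y.elem(train);
    const uword ntr = Xtr.n_rows;

    // training-fold standardization
    vec m(p), s(p);
    for (uword j = 0; j < p; ++j) {
      m(j) = mean(Xtr.col(j));
      Xtr.col(j) -= m(j);
      double sj = (ntr > 1)
        ? std::sqrt(dot(Xtr.col(j), Xtr.col(j)) / (double)(ntr - 1)) : 0.0;
      if (sj < 1e-10) { Xtr.col(j).zeros(); s(j) = 0.0; }
      else { Xtr.col(j) /= sj; s(j) = sj; }
    }
    double ybar = mean(ytr);
    vec ytrc = ytr - ybar;

    mat XtX = Xtr.t() * Xtr;
    vec Xty = Xtr.t() * ytrc;
    mat betas(p, L, fill::zeros);
    cd_path_core(XtX, Xty, ntr, alpha, lambda, betas, tol, max_sweeps);

    // held-out rows through the training transform
    mat Xte = X.rows(test);
    for (uword j = 0; j < p; ++j) {
      Xte.col(j) -= m(j);
      if (s(j) > 0.0) Xte.col(j) /= s(j); else Xte.col(j).zeros();
    }
    vec yte = y.elem(test);
    for (uword l = 0; l < L; ++l) {
      vec pred = ybar + Xte * betas.col(l);
      vec r = yte - pred;
      mse(f - 1, l) = dot(r, r) / (double)yte.n_elem;
    }
  }
  return mse;
}

static vec make_path(double lambda_max, double ratio, int n_values) {
  vec path(n_values);
  const double l0 = std::log(lambda_max), l1 = std::log(lambda_max * ratio);
  for (int i = 0; i < n_values; ++i)
    path(i) = std::exp(l0 + (l1 - l0) * (double)i / (double)(n_values - 1));
  return path;
}

// Bootstrap driver for one penalized method. idx: n x B matrix of 1-based
// row indices (one column per replicate); foldid: n x B fold labels.
// Each replicate re-standardizes its resampled design, builds its own
// lambda path (lambda_max = max_j |x_j'y| / (n * max(alpha, 1e-3))), tunes
// lambda by k-fold CV when retune is true (ties broken toward the larger
// lambda) or reuses fixed_lambda otherwise, and stores the slopes at the
// chosen lambda. Returns estimates (B x p), chosen lambdas, and the count
// of degenerate (constant-column or zero-signal) replicates.
// [[Rcpp::export]]
Rcpp::List cpp_boot_enet(const arma::mat& X, const arma::vec& y,
                         const arma::imat& idx, const arma::imat& foldid,
                         double alpha, int n_lambda, double ratio,
                         bool retune, double fixed_lambda,
                         double tol = 1e-7, double cv_tol = 1e-5,
                         int max_sweeps = 100000) {
  const uword n = X.n_rows, p = X.n_cols, B = idx.n_cols;
  mat est(B, p, fill::zeros);
  vec lambdas(B, fill::zeros);
  uvec degen(B, fill::zeros);

  for (uword b = 0; b < B; ++b) {
    mat Xb(n, p);
    vec yb(n);
    for (uword i = 0; i < n; ++i) {
      const uword r = (uword)idx(i, b) - 1;
      Xb.row(i) = X.row(r);
      yb(i) = y(r);
    }
    uvec dg = standardize_inplace(Xb);
    if (any(dg)) degen(b) = 1;
    vec ybc = yb - mean(yb);
    vec Xty0 = Xb.t() * ybc;
    double lmax = max(abs(Xty0)) / ((double)n * std::max(alpha, 1e-3));
    if (!(lmax > 0.0)) { degen(b) = 1; continue; } // zero-signal resample
    vec path = make_path(lmax, ratio, n_lambda);

    double chosen;
    if (retune) {
      ivec fid = foldid.col(b);
      mat mse = cpp_cv_mse(Xb, yb, alpha, path, fid, cv_tol, max_sweeps);
      rowvec cvm = mean(mse, 0);
      uword best = 0; // path is decreasing: first strict min = largest lambda
      for (uword l = 1; l < path.n_elem; ++l)
        if (cvm(l) < cvm(best)) best = l;
      chosen = path(best);
    } else {
      chosen = fixed_lambda;
    }
    // fit the replicate along its path down to the chosen lambda (warm start)
    vec fitpath;
    if (retune) {
      fitpath = path(find(path >= chosen * (1.0 - 1e-12)));
    } else {
      fitpath = path(find(path > chosen));
      fitpath.resize(fitpath.n_elem + 1);
      fitpath(fitpath.n_elem - 1) = chosen;
    }
    mat XtX = Xb.t() * Xb;
    mat betas(p, fitpath.n_elem, fill::zeros);
    cd_path_core(XtX, Xty0, n, alpha, fitpath, betas, cv_tol, max_sweeps);
    // polish the chosen-lambda solution to the reporting tolerance
    mat polished(p, 1);
    polished.col(0) = betas.col(fitpath.n_elem - 1);
    vec lchosen(1); lchosen(0) = chosen;
    cd_path_core(XtX, Xty0, n, alpha, lchosen, polished, tol, max_sweeps);
    est.row(b) = polished.col(0).t();
    lambdas(b) = chosen;
  }
  return Rcpp::List::create(Rcpp::Named("estimates") = est,
                            Rcpp::Named("lambdas") = lambdas,
                            Rcpp::Named("degenerate") = degen);
}

// Bootstrap driver for OLS (lambda = 0): minimum-norm least squares per
// replicate on the re-standardized resample.
// [[Rcpp::export]]
Rcpp::List cpp_boot_ols(const arma::mat& X, const arma::vec& y,
                        const arma::imat& idx) {
  const uword n = X.n_rows, p = X.n_cols, B = idx.n_cols;
  mat est(B, p, fill::zeros);
  uvec degen(B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    mat Xb(n, p);
    vec yb(n);
    for (uword i = 0; i < n; ++i) {
      const uword r = (uword)idx(i, b) - 1;
      Xb.row(i) = X.row(r);
      yb(i) = y(r);
    }
    uvec dg = standardize_inplace(Xb);
    if (any(dg)) degen(b) = 1;
    vec ybc = yb - mean(yb);
    est.row(b) = (pinv(Xb) * ybc).t();
  }
  return Rcpp::List::create(Rcpp::Named("estimates") = est,
                            Rcpp::Named("degenerate") = degen);
}
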