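#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// Coordinate descent for the glasso column subproblem
//   minimise 0.5 * b' W11 b - s12' b + lam * ||b||_1
// beta is updated in place (warm start).
static void lasso_cd(const mat& W11, const vec& s12, vec& beta,
                     double lam, double thr, int maxit) {
  const uword m = s12.n_elem;
  vec f = W11 * beta;  // maintained fitted value, O(1) residual lookups
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < m; ++k) {
      const double bk = beta(k);
      // partial residual: drop k's own contribution from the fitted value
      const double r = s12(k) - f(k) + W11(k, k) * bk;
      const double bnew = soft_threshold(r, lam) / W11(k, k);
      const double d = bnew - bk;
      if (d != 0.0) {
        beta(k) = bnew;
        f += d * W11.col(k);
        const double ad = std::abs(d);
        if (ad > dmax) dmax = ad;
      }
    }
    if (dmax < thr) break;
  }
}

// Graphical lasso over a descending penalty path, with warm starts.
//
// Maximises  log det K - tr(S K) - lam * sum_{i != j} |K_ij|  (diagonal
// unpenalised, so the working covariance keeps W_ii = S_ii).  Returns, per
// penalty value, the precision matrix K (exact zeros off-diagonal), the
// number of nonzero upper-triangular entries, log det K and tr(S K) --
// everything EBIC model selection needs.
//
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double thr = 1e-8, int maxit = 500,
                           int maxit_lasso = 2000) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  if (S.n_cols != p) Rcpp::stop("S must be square");

  cube K(p, p, nl, fill::zeros);
  vec logdet(nl, fill::zeros);
  vec trSK(nl, fill::zeros);
  ivec nedges(nl, fill::zeros);
  ivec iters(nl, fill::zeros);

  // degenerate 1x1 problem
  if (p == 1) {
    for (uword l = 0; l < nl; ++l) {
      K(0, 0, l) = 1.0 / S(0, 0);
      logdet(l) = -std::log(S(0, 0));
      trSK(l) = 1.0;
    }
    return Rcpp::List::create(
        Rcpp::Named("K") = K, Rcpp::Named("n_edges") = nedges,
        Rcpp::Named("logdet") = logdet, Rcpp::Named("trSK") = trSK,
        Rcpp::Named("iterations") = iters,
        Rcpp::Named("converged") = Rcpp::LogicalVector(nl, true));
  }

  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) sbar += std::abs(S(i, j));
  sbar /= 0.5 * p * (p - 1);
  const double eps = thr * std::max(sbar, 1e-10);
  const double eps_inner = eps;

  mat W = S;            // working covariance, diagonal fixed at S_ii
  mat B(p, p, fill::zeros);  // B.col(j): lasso coefficients of column j

  // index sets "all but j", built once
  std::vector<uvec> idxs(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i)
      if (i != j) idx(c++) = i;
    idxs[j] = idx;
  }

  Rcpp::LogicalVector conv(nl, true);

  for (uword l = 0; l < nl; ++l) {
    const double lam = lambdas(l);
    int it = 0;
    bool done = false;
    for (; it < maxit && !done; ++it) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        const uvec& idx = idxs[j];
        mat W11 = W.submat(idx, idx);
        vec s12 = S.col(j);
        s12.shed_row(j);
        vec beta = B.col(j);
        beta.shed_row(j);
        lasso_cd(W11, s12, beta, lam, eps_inner, maxit_lasso);
        vec w12 = W11 * beta;
        for (uword c = 0; c < p - 1; ++c) {
          const uword i = idx(c);
          const double d = std::abs(W(i, j) - w12(c));
          if (d > dmax) dmax = d;
          W(i, j) = w12(c);
          W(j, i) = w12(c);
          B(i, j) = beta(c);
        }
      }
      if (dmax < eps) done = true;
    }
    iters(l) = it;
    if (!done) conv(l) = false;

    // recover K column-wise from (W, B)
    mat Kl(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = idxs[j];
      double fit = 0.0;
      for (uword c = 0; c < p - 1; ++c) fit += W(idx(c), j) * B(idx(c), j);
      double denom = W(j, j) - fit;
      if (denom < 1e-12) denom = 1e-12;
      const double kjj = 1.0 / denom;
      Kl(j, j) = kjj;
      for (uword c = 0; c < p - 1; ++c) Kl(idx(c), j) = -B(idx(c), j) * kjj;
    }
    // symmetrise; an edge exists only where both column solves agree it does,
    // preserving exact zeros
    mat Ks = 0.5 * (Kl + Kl.t());
    int ne = 0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        if (Kl(i, j) == 0.0 || Kl(j, i) == 0.0) {
          Ks(i, j) = 0.0;
          Ks(j, i) = 0.0;
        } else {
          ++ne;
        }
      }
    }
    nedges(l) = ne;
    K.slice(l) = Ks;

    double val = 0.0, sign = 1.0;
    log_det(val, sign, Ks);
    logdet(l) = (sign > 0) ? val : datum::nan;
    trSK(l) = accu(S % Ks);
  }

  return Rcpp::List::create(
      Rcpp::Named("K") = K, Rcpp::Named("n_edges") = nedges,
      Rcpp::Named("logdet") = logdet, Rcpp::Named("trSK") = trSK,
      Rcpp::Named("iterations") = iters, Rcpp::Named("converged") = conv);
}
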