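// Coordinate-descent lasso on standardized data, driven entirely by the
// p x p Gram (correlation) matrix.  With columns standardized to zero mean
// and unit population variance, the per-coordinate update for the problem
//   min_b (1/2n)||y - Xb||^2 + lambda ||b||_1
// reduces to a soft-threshold of the partial residual correlation, which
// lets neighborhood selection over many subsamples reuse one O(n p^2) Gram
// per subsample instead of touching the data again.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Fit, for every response column i and every lambda on a decreasing path,
// the lasso regression of column i on all other columns.  C is the Gram
// matrix X'X/n of standardized columns (diagonal 1 for non-constant
// columns, all-zero row/col for constant ones).  Coordinates are visited
// in fixed index order; the path is warm-started, so the whole fit is
// deterministic.  Returns a cube with coef(j, i, k) = coefficient of
// predictor j in the regression of response i at lambdas[k].
// [[Rcpp::export]]
arma::cube cd_lasso_path(const arma::mat& C,
                         const arma::vec& lambdas,
                         double tol = 1e-6,
                         int max_sweeps = 10000) {
  const int p = C.n_rows;
  const int K = lambdas.n_elem;
  arma::cube coef(p, p, K, arma::fill::zeros);

  for (int i = 0; i < p; ++i) {
    arma::vec b(p, arma::fill::zeros);        // warm start along the path
    for (int k = 0; k < K; ++k) {
      const double lam = lambdas[k];
      // glmnet-style active-set strategy: after a full sweep, iterate on
      // the nonzero coordinates only, then re-check with a full sweep
      int sweeps_used = 0;
      while (sweeps_used < max_sweeps) {
        double full_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          if (j == i) continue;
          if (C(j, j) == 0.0) { b[j] = 0.0; continue; }  // constant column
          // partial residual correlation of predictor j with response i
          const double cj = arma::dot(C.col(j), b) - b[j]; // C(j,j) == 1
          const double r = C(j, i) - cj;
          const double bj = soft(r, lam);
          const double d = std::abs(bj - b[j]);
          if (d > full_delta) full_delta = d;
          b[j] = bj;
        }
        ++sweeps_used;
        if (full_delta < tol) break;
        arma::uvec active = arma::find(b != 0.0);
        while (sweeps_used < max_sweeps) {
          double act_delta = 0.0;
          for (arma::uword a = 0; a < active.n_elem; ++a) {
            const int j = active[a];
            if (j == i || C(j, j) == 0.0) continue;
            const double cj = arma::dot(C.col(j), b) - b[j];
            const double r = C(j, i) - cj;
            const double bj = soft(r, lam);
            const double d = std::abs(bj - b[j]);
            if (d > act_delta) act_delta = d;
            b[j] = bj;
          }
          ++sweeps_used;
          if (act_delta < tol) break;
        }
      }
      b[i] = 0.0;
      coef.slice(k).col(i) = b;
    }
  }
  return coef;
}

// Symmetrized edge support for StARS: from the coefficient cube of one
// subsample, mark support(i, j, k) = 1 when edge {i, j} is selected at
// lambdas[k] under the OR (any nonzero direction) or AND (both) rule.
// [[Rcpp::export]]
arma::cube symmetrized_support(const arma::cube& coef, bool and_rule = false) {
  const int p = coef.n_rows;
  const int K = coef.n_slices;
  arma::cube support(p, p, K, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j) {
        const bool a = coef(j, i, k) != 0.0;
        const bool bb = coef(i, j, k) != 0.0;
        const bool sel = and_rule ? (a && bb) : (a || bb);
        if (sel) {
          support(i, j, k) = 1.0;
          support(j, i, k) = 1.0;
        }
      }
    }
  }
  return support;
}
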