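#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net on sufficient statistics.
// Minimizes (1/2) b'Gb - c'b + lambda*alpha*||b||_1 + (lambda*(1-alpha)/2)*||b||_2^2
// with G = X'X/n and c = X'y/n, i.e. the 1/(2n) residual-sum-of-squares scaling.
// [[Rcpp::export]]
List cd_enet_gram(NumericMatrix G, NumericVector c, double lambda, double alpha,
                  NumericVector beta0, double tol, int maxit) {
  int p = c.size();
  NumericVector beta = clone(beta0);
  double l1 = lambda * alpha;
  double l2 = lambda * (1.0 - alpha);
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      double gb = 0.0;
      for (int k = 0; k < p; ++k) gb += G(j, k) * beta[k];
      double rj = c[j] - gb + G(j, j) * beta[j];
      double bnew = soft(rj, l1) / (G(j, j) + l2);
      double d = std::abs(bnew - beta[j]);
      if (d > maxdiff) maxdiff = d;
      beta[j] = bnew;
    }
    if (maxdiff < tol) { converged = true; ++it; break; }
  }
  return List::create(_["beta"] = beta, _["iter"] = it, _["converged"] = converged);
}

// Coordinate descent for summary-statistic penalized regression on one LD block.
// Minimizes (up to the constant y'y)
//   (1-s) b'Rb - 2 b'r + s b'b + 2*lambda*||b||_1
// where R is the block correlation matrix from the reference panel. The
// coordinate update is soft(r_j - (1-s) * sum_{k != j} R_jk b_k, lambda) /
// ((1-s) R_jj + s); with R_jj = 1 the denominator is 1.
// [[Rcpp::export]]
List cd_lassosum_block(NumericMatrix R, NumericVector r, double lambda, double s,
                       NumericVector beta0, double tol, int maxit) {
  int p = r.size();
  NumericVector beta = clone(beta0);
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      double rb = 0.0;
      for (int k = 0; k < p; ++k) if (k != j) rb += R(j, k) * beta[k];
      double z = r[j] - (1.0 - s) * rb;
      double bnew = soft(z, lambda) / ((1.0 - s) * R(j, j) + s);
      double d = std::abs(bnew - beta[j]);
      if (d > maxdiff) maxdiff = d;
      beta[j] = bnew;
    }
    if (maxdiff < tol) { converged = true; ++it; break; }
  }
  return List::create(_["beta"] = beta, _["iter"] = it, _["converged"] = converged);
}
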