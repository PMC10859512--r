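#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft_thr(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One graphical-lasso fit by block coordinate descent over columns of the
// working covariance W (diagonal unpenalised, so diag(W) == diag(S) stays
// fixed).  Each block solves the lasso subproblem
//   min_b  0.5 b' W11 b - s12' b + lambda ||b||_1
// by cyclic coordinate descent.  W and Beta act as warm starts and are
// updated in place.
static void glasso_one(const arma::mat& S, double lambda, double tol,
                       int maxit, arma::mat& W, arma::mat& Beta,
                       int& iters, bool& converged, double& final_change) {
  const int p = (int)S.n_rows;
  double offavg = 0.0;
  int cnt = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { offavg += std::fabs(S(i, j)); ++cnt; }
  offavg = cnt > 0 ? offavg / cnt : 0.0;
  const double thr = tol * std::max(offavg, 1e-12);
  const double inner_thr = thr * 0.1;

  iters = 0;
  converged = false;
  final_change = 0.0;
  if (p == 1) { converged = true; return; }

  arma::vec beta(p - 1), s12(p - 1), w12(p - 1);
  arma::mat W11(p - 1, p - 1);

  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      int r = 0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        s12(r) = S(i, j);
        beta(r) = Beta(i, j);
        int c = 0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          W11(r, c) = W(i, k);
          ++c;
        }
        ++r;
      }
      for (int inner = 0; inner < 10000; ++inner) {
        double del = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double g = s12(k) - arma::dot(W11.col(k), beta) +
                     W11(k, k) * beta(k);
          double bnew = soft_thr(g, lambda) / W11(k, k);
          double d = std::fabs(bnew - beta(k));
          if (d > del) del = d;
          beta(k) = bnew;
        }
        if (del < inner_thr) break;
      }
      w12 = W11 * beta;
      r = 0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(w12(r) - W(i, j));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w12(r);
        W(j, i) = w12(r);
        Beta(i, j) = beta(r);
        ++r;
      }
    }
    iters = it + 1;
    final_change = maxdiff;
    if (maxdiff < thr) { converged = true; break; }
  }
}

// Back out the precision matrix from the converged working covariance and
// the per-column regression coefficients:
//   K_jj = 1 / (W_jj - w12' beta_j),  K_.j = -beta_j K_jj.
static arma::mat recover_K(const arma::mat& W, const arma::mat& Beta) {
  const int p = (int)W.n_rows;
  arma::mat K(p, p, arma::fill::zeros);
  if (p == 1) { K(0, 0) = 1.0 / W(0, 0); return K; }
  for (int j = 0; j < p; ++j) {
    double dwb = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) dwb += W(i, j) * Beta(i, j);
    double kjj = 1.0 / (W(j, j) - dwb);
    K(j, j) = kjj;
    for (int i = 0; i < p; ++i)
      if (i != j) K(i, j) = -Beta(i, j) * kjj;
  }
  return 0.5 * (K + K.t());
}

// [[Rcpp::export]]
List glasso_cpp(const arma::mat& S, double lambda, double tol, int maxit) {
  arma::mat W = S;
  arma::mat Beta(S.n_rows, S.n_cols, arma::fill::zeros);
  int iters;
  bool conv;
  double change;
  glasso_one(S, lambda, tol, maxit, W, Beta, iters, conv, change);
  return List::create(_["K"] = recover_K(W, Beta), _["W"] = W,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["change"] = change);
}

// Fit a whole decreasing penalty path with warm starts carried along.
// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double tol, int maxit) {
  arma::mat W = S;
  arma::mat Beta(S.n_rows, S.n_cols, arma::fill::zeros);
  const int m = (int)lambdas.n_elem;
  List Ks(m);
  IntegerVector iters(m);
  LogicalVector conv(m);
  NumericVector change(m);
  for (int l = 0; l < m; ++l) {
    int it;
    bool cv;
    double ch;
    glasso_one(S, lambdas(l), tol, maxit, W, Beta, it, cv, ch);
    Ks[l] = recover_K(W, Beta);
    iters[l] = it;
    conv[l] = cv;
    change[l] = ch;
  }
  return List::create(_["K"] = Ks, _["iterations"] = iters,
                      _["converged"] = conv, _["change"] = change);
}
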