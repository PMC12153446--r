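// Graphical lasso by block coordinate descent over the covariance (dual)
// with lasso subproblems solved per column, as in the reference algorithm.
// Penalty applies to off-diagonal entries only, so lambda >= max|s_ij|
// yields an exactly diagonal precision matrix.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// coordinate descent for: min_b 1/2 b'Vb - u'b + lambda*||b||_1
static void lasso_cd(const mat &V, const vec &u, const double lambda,
                     vec &b, const double tol, const int max_iter) {
  const unsigned int p = u.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (unsigned int j = 0; j < p; ++j) {
      const double old = b(j);
      // partial residual; V is symmetric with positive diagonal
      const double x = u(j) - dot(V.col(j), b) + V(j, j) * old;
      double bnew = 0.0;
      if (x > lambda) bnew = (x - lambda) / V(j, j);
      else if (x < -lambda) bnew = (x + lambda) / V(j, j);
      b(j) = bnew;
      const double d = std::fabs(bnew - old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) break;
  }
}

struct GlassoFit {
  mat Theta;
  mat W;
  mat B;        // (p-1) x p regression coefficients (warm-start state)
  int iters;
  double delta; // final mean absolute change in W
};

static GlassoFit glasso_engine(const mat &S, const double lambda,
                               const double tol, const int max_iter,
                               const mat *W0, const mat *B0) {
  const unsigned int p = S.n_rows;
  GlassoFit fit;
  // off-diagonal-only penalty: the working covariance keeps the sample
  // diagonal (no lambda inflation)
  mat W = (W0 != nullptr) ? *W0 : mat(S);
  W.diag() = S.diag();
  mat B = (B0 != nullptr) ? *B0 : mat(p > 1 ? p - 1 : 1, p, fill::zeros);

  if (p == 1) {
    fit.Theta = mat(1, 1, fill::value(1.0 / W(0, 0)));
    fit.W = W; fit.B = B; fit.iters = 0; fit.delta = 0.0;
    return fit;
  }

  const double inner_tol = tol * 0.1 + 1e-12;
  const int inner_max = 1000;
  int it = 0;
  double delta = datum::inf;
  for (it = 1; it <= max_iter; ++it) {
    double sumchange = 0.0;
    for (unsigned int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      unsigned int k = 0;
      for (unsigned int i = 0; i < p; ++i) if (i != j) idx(k++) = i;
      mat W11 = W(idx, idx);
      vec s12(p - 1);
      for (unsigned int i = 0; i < p - 1; ++i) s12(i) = S(idx(i), j);
      vec b = B.col(j);
      lasso_cd(W11, s12, lambda, b, inner_tol, inner_max);
      B.col(j) = b;
      vec w12 = W11 * b;
      for (unsigned int i = 0; i < p - 1; ++i) {
        sumchange += std::fabs(W(idx(i), j) - w12(i));
        W(idx(i), j) = w12(i);
        W(j, idx(i)) = w12(i);
      }
    }
    delta = sumchange / (double)(p * (p - 1));
    if (delta < tol) break;
  }

  // recover Theta from the final regressions
  mat Theta(p, p, fill::zeros);
  for (unsigned int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    unsigned int k = 0;
    for (unsigned int i = 0; i < p; ++i) if (i != j) idx(k++) = i;
    const vec b = B.col(j);
    double q = W(j, j);
    for (unsigned int i = 0; i < p - 1; ++i) q -= W(idx(i), j) * b(i);
    const double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (unsigned int i = 0; i < p - 1; ++i) Theta(idx(i), j) = -b(i) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());
  // absorb numerical noise; keeps the support symmetric
  for (unsigned int i = 0; i < p; ++i)
    for (unsigned int j = 0; j < p; ++j)
      if (i != j && std::fabs(Theta(i, j)) < 1e-10) Theta(i, j) = 0.0;

  fit.Theta = Theta; fit.W = W; fit.B = B;
  fit.iters = (it > max_iter) ? max_iter : it;
  fit.delta = delta;
  return fit;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat &S, const double lambda,
                      const double tol, const int max_iter) {
  GlassoFit fit = glasso_engine(S, lambda, tol, max_iter, nullptr, nullptr);
  return Rcpp::List::create(
    Rcpp::Named("theta") = fit.Theta,
    Rcpp::Named("w") = fit.W,
    Rcpp::Named("iters") = fit.iters,
    Rcpp::Named("delta") = fit.delta);
}

// fit a decreasing lambda path with warm starts
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat &S, const arma::vec &lambdas,
                           const double tol, const int max_iter) {
  const unsigned int m = lambdas.n_elem;
  Rcpp::List thetas(m);
  Rcpp::IntegerVector iters(m);
  mat W, B;
  bool warm = false;
  for (unsigned int k = 0; k < m; ++k) {
    GlassoFit fit = glasso_engine(S, lambdas(k), tol, max_iter,
                                  warm ? &W : nullptr, warm ? &B : nullptr);
    thetas[k] = fit.Theta;
    iters[k] = fit.iters;
    W = fit.W; B = fit.B; warm = true;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("iters") = iters);
}
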