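// Compiled kernel for the resampled-fitness hot loop: fit a univariate
// NIPALS PLS model on a calibration subset and predict a validation subset.
// The genetic-algorithm selector evaluates this hundreds of thousands of
// times per ensemble; everything else in the package uses the R NIPALS.
// Must agree numerically with the R implementation (tested against it).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// cal/val are 0-based row indices into X. Components are capped at what
// the data support; a fully degenerate X block (constant after centring)
// yields the mean model rather than an error, so the caller's search loop
// never has to handle exceptions.
// [[Rcpp::export(name = ".pls_fit_predict_cpp")]]
Rcpp::List pls_fit_predict_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::uvec& cal, const arma::uvec& val,
                               int ncomp) {
  mat Xc = X.rows(cal);
  rowvec xm = mean(Xc, 0);
  Xc.each_row() -= xm;
  vec yc = y.elem(cal);
  double ym = mean(yc);
  yc -= ym;
  const uword p = Xc.n_cols;

  mat W(p, ncomp), P(p, ncomp);
  vec q(ncomp);
  vec res = yc;
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = Xc.t() * res;
    double nw = norm(w);
    if (nw < 1e-300) break;           // nothing left to extract
    w /= nw;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < 1e-300) break;
    vec pl = Xc.t() * t / tt;
    double qq = dot(res, t) / tt;
    Xc -= t * pl.t();
    res -= t * qq;
    W.col(a) = w;
    P.col(a) = pl;
    q(a) = qq;
    ++used;
  }

  vec B(p, fill::zeros);
  if (used > 0) {
    mat Wu = W.cols(0, used - 1);
    mat Pu = P.cols(0, used - 1);
    vec qu = q.subvec(0, used - 1);
    vec sol;
    if (solve(sol, Pu.t() * Wu, qu, solve_opts::no_approx))
      B = Wu * sol;
    else
      res = yc;                       // singular projection: mean model
  }

  mat Xv = X.rows(val);
  Xv.each_row() -= xm;
  vec pred = Xv * B + ym;

  return Rcpp::List::create(
    Rcpp::Named("msec") = dot(res, res) / (double)cal.n_elem,
    Rcpp::Named("pred") = pred);
}
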