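// Exhaustive knot search for the continuous four-segment piecewise-linear
// least-squares fit of an LV time-volume curve.
//
// The model is parameterised with a truncated-power (hinge) basis
//   v(t) = b0 + b1*t + c1*(t - k1)_+ + c2*(t - k2)_+ + c3*(t - k3)_+
// with interior knots restricted to the frame grid. For every admissible
// frame triple k1 < k2 < k3 the 5-parameter normal equations are solved
// from a precomputed Gram matrix, so the full search over ~C(n-1, 3)
// candidates costs one 5x5 solve each.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List plr_search_cpp(const arma::vec& t, const arma::vec& y) {
  const int n = t.n_elem;
  const int m = n - 1;  // candidate interior knots: frames 2..n (t[1..n-1])
  if (n < 8) Rcpp::stop("too few frames for a four-segment fit");

  arma::mat X(n, m + 2);
  X.col(0).ones();
  X.col(1) = t;
  for (int j = 0; j < m; ++j) {
    arma::vec h = t - t[j + 1];
    h.transform([](double v) { return v > 0.0 ? v : 0.0; });
    X.col(j + 2) = h;
  }
  const arma::mat G = X.t() * X;
  const arma::vec g = X.t() * y;
  const double yty = arma::dot(y, y);

  double best = arma::datum::inf;
  arma::uvec best_knots(3, arma::fill::zeros);
  arma::vec best_beta(5, arma::fill::zeros);

  arma::uvec idx(5);
  idx[0] = 0; idx[1] = 1;
  arma::mat M(5, 5);
  arma::vec v(5), b(5);
  for (int i = 0; i < m - 2; ++i) {
    for (int j = i + 1; j < m - 1; ++j) {
      for (int k = j + 1; k < m; ++k) {
        idx[2] = i + 2; idx[3] = j + 2; idx[4] = k + 2;
        M = G.submat(idx, idx);
        v = g.elem(idx);
        if (!arma::solve(b, M, v, arma::solve_opts::likely_sympd +
                                      arma::solve_opts::no_approx))
          continue;
        const double rss = yty - arma::dot(v, b);
        if (rss < best) {
          best = rss;
          best_knots = {static_cast<arma::uword>(i + 1),
                        static_cast<arma::uword>(j + 1),
                        static_cast<arma::uword>(k + 1)};
          best_beta = b;
        }
      }
    }
  }
  if (!std::isfinite(best)) Rcpp::stop("piecewise-linear fit failed");
  if (best < 0.0) best = 0.0;  // guard against round-off

  return Rcpp::List::create(
      Rcpp::Named("knot_frames") = best_knots + 1,  // 1-based frame index
      Rcpp::Named("coef") = best_beta,
      Rcpp::Named("rss") = best);
}
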