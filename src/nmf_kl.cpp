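// Multiplicative-update NMF minimizing generalized Kullback-Leibler
// divergence (Brunet variant). The inner loop is compiled because rank
// sweeps with many random restarts dominate the module-discovery runtime.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_objective(const mat& V, const mat& WH, double eps) {
  // sum(V log(V / WH) - V + WH), with 0 log 0 = 0
  mat ratio = (V + eps) / (WH + eps);
  return accu(V % log(ratio) - V + WH);
}

// [[Rcpp::export]]
Rcpp::List nmf_kl_run(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  const double eps = 1e-12;
  std::vector<double> trace;
  double prev = datum::inf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat WH = W * H;
    WH.transform([eps](double x) { return x > eps ? x : eps; });
    mat Q = V / WH;
    H %= W.t() * Q;
    vec wsum = sum(W, 0).t();
    wsum.transform([eps](double x) { return x > eps ? x : eps; });
    H.each_col() /= wsum;

    WH = W * H;
    WH.transform([eps](double x) { return x > eps ? x : eps; });
    Q = V / WH;
    W %= Q * H.t();
    rowvec hsum = sum(H, 1).t();
    hsum.transform([eps](double x) { return x > eps ? x : eps; });
    W.each_row() /= hsum;

    if (iter % check_every == 0 || iter == max_iter) {
      double obj = kl_objective(V, W * H, eps);
      trace.push_back(obj);
      if (std::isfinite(prev) &&
          std::fabs(prev - obj) <= tol * (std::fabs(prev) + eps)) {
        prev = obj;
        break;
      }
      prev = obj;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective") = kl_objective(V, W * H, eps),
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = std::min(iter, max_iter));
}
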