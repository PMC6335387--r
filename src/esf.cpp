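#include <Rcpp.h>
using namespace Rcpp;

// Elementary symmetric functions by the summation recursion, optionally
// skipping one or two positions.  Orders 0..m where m = #items used.
static std::vector<double> esf_skip(const NumericVector& eps, int skip1, int skip2) {
  int n = eps.size();
  int m = n - (skip1 >= 0 ? 1 : 0) - (skip2 >= 0 ? 1 : 0);
  std::vector<double> g(m + 1, 0.0);
  g[0] = 1.0;
  int used = 0;
  for (int i = 0; i < n; ++i) {
    if (i == skip1 || i == skip2) continue;
    ++used;
    for (int r = used; r >= 1; --r) g[r] += eps[i] * g[r - 1];
  }
  return g;
}

// [[Rcpp::export]]
NumericVector esf_cpp(NumericVector eps) {
  std::vector<double> g = esf_skip(eps, -1, -1);
  return NumericVector(g.begin(), g.end());
}

// Column i holds the ESFs of eps with position i removed (orders 0..n-1);
// d gamma_r / d eps_i equals column i at order r-1.
// [[Rcpp::export]]
NumericMatrix esf_minus_one_cpp(NumericVector eps) {
  int n = eps.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    std::vector<double> gi = esf_skip(eps, i, -1);
    for (int r = 0; r < n; ++r) out(r, i) = gi[r];
  }
  return out;
}

// Conditional log-likelihood of the Rasch model plus analytic gradient and
// Hessian in beta = -log(eps).  cnt holds raw-score frequencies for scores
// 0..n (extreme scores must be zero), stot the item margins of the retained
// persons.  pi1(i, r) is the conditional probability of a positive response
// on item i given raw score r.
// [[Rcpp::export]]
List cml_derivs_cpp(NumericVector eps, NumericVector cnt, NumericVector stot) {
  int n = eps.size();
  std::vector<double> g = esf_skip(eps, -1, -1);
  NumericMatrix pi1(n, n + 1);
  std::vector< std::vector<double> > gi(n);
  for (int i = 0; i < n; ++i) {
    gi[i] = esf_skip(eps, i, -1);
    for (int r = 1; r <= n - 1; ++r)
      pi1(i, r) = eps[i] * gi[i][r - 1] / g[r];
  }
  double cll = 0.0;
  for (int r = 1; r <= n - 1; ++r)
    if (cnt[r] > 0) cll -= cnt[r] * std::log(g[r]);
  NumericVector grad(n);
  for (int i = 0; i < n; ++i) {
    cll += stot[i] * std::log(eps[i]);
    double acc = -stot[i];
    for (int r = 1; r <= n - 1; ++r) acc += cnt[r] * pi1(i, r);
    grad[i] = acc;
  }
  NumericMatrix H(n, n);
  for (int i = 0; i < n; ++i) {
    double d = 0.0;
    for (int r = 1; r <= n - 1; ++r)
      d -= cnt[r] * pi1(i, r) * (1.0 - pi1(i, r));
    H(i, i) = d;
    for (int j = i + 1; j < n; ++j) {
      std::vector<double> gij = esf_skip(eps, i, j);
      double acc = 0.0;
      for (int r = 1; r <= n - 1; ++r) {
        double pij = (r >= 2) ? eps[i] * eps[j] * gij[r - 2] / g[r] : 0.0;
        acc += cnt[r] * (pi1(i, r) * pi1(j, r) - pij);
      }
      H(i, j) = acc;
      H(j, i) = acc;
    }
  }
  return List::create(_["loglik"] = cll, _["grad"] = grad, _["hessian"] = H);
}
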