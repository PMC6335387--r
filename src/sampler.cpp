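#include <Rcpp.h>
using namespace Rcpp;

// Rectangle-swap Markov chain on the set of 0/1 matrices with fixed row and
// column sums.  A proposal draws two row and two column indices
// independently with replacement (coinciding indices give a hold move,
// which keeps the chain aperiodic even when every distinct tetrad is
// swappable); if the 2x2 submatrix is a checkerboard it is flipped.  The
// proposal kernel is symmetric, so the stationary law is uniform on the
// margin-fixed set.  Uses R's RNG stream.
static void run_chain(IntegerMatrix& x, double nprop) {
  int N = x.nrow(), n = x.ncol();
  long long steps = (long long) nprop;
  for (long long t = 0; t < steps; ++t) {
    int i1 = (int)(unif_rand() * N); if (i1 == N) i1 = N - 1;
    int i2 = (int)(unif_rand() * N); if (i2 == N) i2 = N - 1;
    int j1 = (int)(unif_rand() * n); if (j1 == n) j1 = n - 1;
    int j2 = (int)(unif_rand() * n); if (j2 == n) j2 = n - 1;
    if (i1 == i2 || j1 == j2) continue;
    int a = x(i1, j1), b = x(i1, j2), c = x(i2, j1), d = x(i2, j2);
    if (a == d && b == c && a != b) {
      x(i1, j1) = b; x(i1, j2) = a; x(i2, j1) = d; x(i2, j2) = c;
    }
  }
}

// [[Rcpp::export]]
List sample_margins_cpp(IntegerMatrix x0, int B, double burn_in, double thin) {
  IntegerMatrix x = clone(x0);
  List out(B);
  run_chain(x, burn_in);
  for (int s = 0; s < B; ++s) {
    run_chain(x, thin);
    out[s] = clone(x);
  }
  return out;
}
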