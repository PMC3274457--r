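#include <Rcpp.h>
using namespace Rcpp;

// Triangle bound smoothing of a symmetric distance-bound matrix pair.
// Upper bounds: Floyd-Warshall shortest paths (u_ij <= u_ik + u_kj).
// Lower bounds: inverse triangle inequality l_ij >= max(l_ik - u_kj,
// l_kj - u_ik), iterated Gauss-Seidel style until a fixed point or
// max_sweeps. Uppers are smoothed first; lower sweeps use smoothed uppers.
// [[Rcpp::export]]
List smooth_bounds_cpp(NumericMatrix lower, NumericMatrix upper,
                       int max_sweeps) {
  int n = upper.nrow();
  NumericMatrix U(clone(upper));
  NumericMatrix L(clone(lower));

  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        double via = uik + U(k, j);
        if (via < U(i, j)) U(i, j) = via;
      }
    }
  }

  bool converged = false;
  int sweep = 0;
  while (!converged && sweep < max_sweeps) {
    converged = true;
    for (int k = 0; k < n; ++k) {
      for (int i = 0; i < n; ++i) {
        if (i == k) continue;
        double lik = L(i, k);
        for (int j = 0; j < n; ++j) {
          if (j == i || j == k) continue;
          double cand = lik - U(k, j);
          double cand2 = L(k, j) - U(i, k);
          if (cand2 > cand) cand = cand2;
          if (cand > L(i, j)) {
            L(i, j) = cand;
            L(j, i) = cand;
            converged = false;
          }
        }
      }
    }
    ++sweep;
  }

  return List::create(_["lower"] = L, _["upper"] = U,
                      _["converged"] = converged, _["sweeps"] = sweep);
}
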