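// Context-image (CI) encoding: for a target voxel v, histogram the tuples
// (S(v'), FCM[v](v')) over the neighbourhood N(v) = {v' : FCM[v](v') > eps}
// on log10-spaced edges. Values above an axis upper bound land in that axis's
// highest bin; values at or below the lower bound are dropped. Bin intervals
// are right-closed (e_i, e_{i+1}], so a value exactly on an interior edge
// goes to the lower-indexed bin.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {
// edges has length nb + 1; returns -1 (drop) or 0 .. nb-1
inline int bin_log(double lx, const double* e, int nb) {
  if (lx <= e[0]) return -1;
  if (lx > e[nb]) return nb - 1;
  for (int i = 0; i < nb; ++i)
    if (lx <= e[i + 1]) return i;
  return nb - 1;
}
}

// signal: slice values (length n); bank: n x K matrix, column k = FCM of
// target k over the plane. Returns K x (nb_s * nb_f) integer count matrix,
// feature layout row-major with the signal axis as rows:
// column index = s_bin * nb_f + f_bin (0-based).
// [[Rcpp::export]]
IntegerMatrix encode_ci_cpp(NumericVector signal, NumericMatrix bank,
                            NumericVector s_edges, NumericVector f_edges,
                            double eps) {
  int n = signal.size();
  if (bank.nrow() != n) stop("signal and FCM bank grids differ");
  int K = bank.ncol();
  int nb_s = s_edges.size() - 1, nb_f = f_edges.size() - 1;
  IntegerMatrix out(K, nb_s * nb_f);
  const double* se = &s_edges[0];
  const double* fe = &f_edges[0];

  for (int k = 0; k < K; ++k) {
    const double* col = &bank[0] + (size_t)n * k;
    for (int v = 0; v < n; ++v) {
      double f = col[v];
      if (!(f > eps)) continue;                 // outside N(v)
      int fb = bin_log(std::log10(f), fe, nb_f);
      if (fb < 0) continue;
      double s = signal[v];
      if (!(s > 0)) continue;
      int sb = bin_log(std::log10(s), se, nb_s);
      if (sb < 0) continue;
      out(k, sb * nb_f + fb)++;
    }
  }
  return out;
}
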