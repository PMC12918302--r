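#include <Rcpp.h>
using namespace Rcpp;

// Row-wise minimum of the implied squared-distance matrix
//   d2[i, j] = usq[i] + lsq[j] - 2 * G[i, j],
// where G = U %*% t(L) is computed in R with BLAS. Only the j-dependent part
// is minimised here; the caller adds usq afterwards. One cache-friendly pass
// over G, no n x m allocation beyond G itself (which the caller chunks).
// [[Rcpp::export(name = ".rowmin_d2")]]
NumericVector rowmin_d2(NumericMatrix G, NumericVector lsq) {
  const int n = G.nrow();
  const int m = G.ncol();
  if (lsq.size() != m) stop("lsq length must match ncol(G)");
  NumericVector out(n, R_PosInf);
  double *op = out.begin();
  const double *gp = G.begin();
  for (int j = 0; j < m; ++j) {
    const double c = lsq[j];
    const double *g = gp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double v = c - 2.0 * g[i];
      if (v < op[i]) op[i] = v;
    }
  }
  return out;
}
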