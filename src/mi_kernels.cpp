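#include <Rcpp.h>
using namespace Rcpp;

// Residue codes: 1..20 for the amino acids, 0 for gap or 'X' (excluded from
// all frequency counts). Weights are identity-cluster weights; frequencies
// are proper because every statistic normalises by the summed weight of the
// sequences that actually contribute.

// Weighted mutual information, in nats, for every unordered pair of the
// requested columns. `pc_total` is the total pseudocount mass spread flat
// over the 400 cells of each pair's joint table.
// Returns the upper triangle in (1,2),(1,3),...,(2,3),... order.
// [[Rcpp::export]]
NumericVector mi_pairs_kernel(const IntegerMatrix& X, const NumericVector& w,
                              const IntegerVector& cols, double pc_total) {
  const int n = X.nrow();
  const int m = cols.size();
  if (m < 2) stop("need at least two columns");
  NumericVector out((R_xlen_t)m * (m - 1) / 2);
  std::vector<double> joint(400);
  std::vector<double> pa(20), pb(20);
  const double pc_cell = pc_total / 400.0;
  R_xlen_t k = 0;
  for (int ii = 0; ii < m - 1; ++ii) {
    const int ci = cols[ii] - 1;
    for (int jj = ii + 1; jj < m; ++jj, ++k) {
      const int cj = cols[jj] - 1;
      std::fill(joint.begin(), joint.end(), 0.0);
      double tot = pc_total;
      for (int r = 0; r < n; ++r) {
        const int a = X(r, ci), b = X(r, cj);
        if (a > 0 && b > 0) {
          joint[(a - 1) * 20 + (b - 1)] += w[r];
          tot += w[r];
        }
      }
      if (tot <= 0.0) { out[k] = 0.0; continue; }
      std::fill(pa.begin(), pa.end(), 0.0);
      std::fill(pb.begin(), pb.end(), 0.0);
      for (int a = 0; a < 20; ++a)
        for (int b = 0; b < 20; ++b) {
          const double v = joint[a * 20 + b] + pc_cell;
          pa[a] += v;
          pb[b] += v;
        }
      double mi = 0.0;
      for (int a = 0; a < 20; ++a) {
        if (pa[a] <= 0.0) continue;
        for (int b = 0; b < 20; ++b) {
          const double v = joint[a * 20 + b] + pc_cell;
          if (v > 0.0 && pb[b] > 0.0)
            mi += (v / tot) * std::log(v * tot / (pa[a] * pb[b]));
        }
      }
      out[k] = (mi < 0.0 && mi > -1e-12) ? 0.0 : mi; // clamp fp noise
    }
  }
  return out;
}

// Per-column weighted mutual information between residue identity and a
// two-level group label (g: 1 or 2; 0 = unassigned, skipped). A sequence
// contributes to a column only where it is non-gap; weights renormalise
// per column through the joint-total division.
// [[Rcpp::export]]
NumericVector group_mi_kernel(const IntegerMatrix& X, const NumericVector& w,
                              const IntegerVector& g) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  double joint[20][2];
  for (int c = 0; c < p; ++c) {
    std::fill(&joint[0][0], &joint[0][0] + 40, 0.0);
    double tot = 0.0;
    for (int r = 0; r < n; ++r) {
      const int a = X(r, c), gg = g[r];
      if (a > 0 && gg > 0) {
        joint[a - 1][gg - 1] += w[r];
        tot += w[r];
      }
    }
    if (tot <= 0.0) { out[c] = 0.0; continue; }
    double pa[20] = {0.0}, pg[2] = {0.0};
    for (int a = 0; a < 20; ++a) {
      pa[a] = joint[a][0] + joint[a][1];
      pg[0] += joint[a][0];
      pg[1] += joint[a][1];
    }
    double mi = 0.0;
    for (int a = 0; a < 20; ++a)
      for (int b = 0; b < 2; ++b) {
        const double v = joint[a][b];
        if (v > 0.0)
          mi += (v / tot) * std::log(v * tot / (pa[a] * pg[b]));
      }
    out[c] = (mi < 0.0 && mi > -1e-12) ? 0.0 : mi;
  }
  return out;
}
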