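#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-focal-cell segregation scores. For every focal cell i (focal[i] true),
// neighbours are all *other* cells within `radius` (centre-to-centre,
// periodic-aware in x when requested). With normalize = TRUE the score is the
// activity-weighted same-colour frequency sum(g*m)/sum(m); with FALSE it is
// the literal mean product sum(g*m)/N. Cells that are not focal, or whose
// neighbourhood carries no activity (or no neighbours), get NA.
// [[Rcpp::export]]
NumericVector seg_scores_cpp(NumericVector x, NumericVector y,
                             IntegerVector color, NumericVector m,
                             LogicalVector focal, double radius,
                             bool periodic_x, double width, bool normalize) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    if (!focal[i]) continue;
    double sm = 0.0, tm = 0.0;
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j];
      if (periodic_x) dx -= width * std::round(dx / width);
      double dy = y[i] - y[j];
      if (dx * dx + dy * dy > r2) continue;
      ++cnt;
      tm += m[j];
      if (color[j] == color[i]) sm += m[j];
    }
    if (normalize) {
      if (tm > 0.0) out[i] = sm / tm;
    } else {
      if (cnt > 0) out[i] = sm / cnt;
    }
  }
  return out;
}

// Distance-rule bulk mask: a node is bulk iff its centre is farther than h
// from the centre of every biomass-bearing node. Computed by stamping
// exclusion disks around occupied nodes; x wraps when periodic.
// [[Rcpp::export]]
LogicalMatrix radial_bulk_cpp(LogicalMatrix occ, double h_nodes,
                              bool periodic_x = false) {
  int nx = occ.nrow(), ny = occ.ncol();
  LogicalMatrix bulk(nx, ny);
  std::fill(bulk.begin(), bulk.end(), true);
  int w = (int)std::ceil(h_nodes);
  double h2 = h_nodes * h_nodes;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!occ(i, j)) continue;
      for (int dj = -w; dj <= w; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -w; di <= w; ++di) {
          int ii = i + di;
          if (periodic_x) { ii %= nx; if (ii < 0) ii += nx; }
          else if (ii < 0 || ii >= nx) continue;
          if (di * di + dj * dj <= h2) bulk(ii, jj) = false;
        }
      }
    }
  return bulk;
}
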