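#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// xorshift32: reproducible sweep-order shuffles decoupled from R's RNG stream
static inline uint32_t xs32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5; return s;
}

struct BinGrid {
  double x0, y0, bin;
  int nbx, nby;
  bool wrap;
  double width;
  std::vector<int> head;   // first cell index per bin, -1 if empty
  std::vector<int> nxt;    // linked list over cells
  BinGrid(int n) : nxt(n, -1) {}
  inline int bx(double x) const {
    int b = (int)std::floor((x - x0) / bin);
    if (wrap) { b %= nbx; if (b < 0) b += nbx; }
    else { if (b < 0) b = 0; if (b >= nbx) b = nbx - 1; }
    return b;
  }
  inline int by(double y) const {
    int b = (int)std::floor((y - y0) / bin);
    if (b < 0) b = 0; if (b >= nby) b = nby - 1;
    return b;
  }
  void build(const std::vector<double> &x, const std::vector<double> &y) {
    head.assign((size_t)nbx * nby, -1);
    for (int i = (int)x.size() - 1; i >= 0; --i) {
      int b = by(y[i]) * nbx + bx(x[i]);
      nxt[i] = head[b];
      head[b] = i;
    }
  }
};

// Pairwise hard-disk overlap relaxation ("shoving"). Each overlapping pair is
// displaced along the centre-to-centre axis, each cell by half the overlap,
// in randomized order per sweep; cells pushed below the floor are projected
// back onto y = r. Lateral boundary either periodic on [0, width) or open.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericVector x_, NumericVector y_, NumericVector r_,
                        double width, bool periodic_x, bool floor_y,
                        double tol, int max_sweeps, int seed) {
  int n = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> y(y_.begin(), y_.end());
  std::vector<double> r(r_.begin(), r_.end());
  if (n <= 1) {
    return List::create(_["x"] = x_, _["y"] = y_, _["sweeps"] = 0,
                        _["max_overlap"] = 0.0, _["converged"] = true);
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (r[i] > rmax) rmax = r[i];

  uint32_t rng = (uint32_t)seed; if (rng == 0) rng = 88172645u;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  BinGrid g(n);
  g.bin = 2.0 * rmax + 1e-9;
  g.wrap = periodic_x;
  g.width = width;

  double max_ov = 0.0;
  int sweep = 0;
  bool converged = false;

  // clean residual scan: largest pairwise overlap of the current configuration
  auto residual_scan = [&]() {
    g.build(x, y);
    double resid = 0.0;
    for (int i = 0; i < n; ++i) {
      int bxi = g.bx(x[i]), byi = g.by(y[i]);
      for (int dby = -1; dby <= 1; ++dby) {
        int byn = byi + dby;
        if (byn < 0 || byn >= g.nby) continue;
        for (int dbx = -1; dbx <= 1; ++dbx) {
          int bxn = bxi + dbx;
          if (g.wrap) { bxn %= g.nbx; if (bxn < 0) bxn += g.nbx; }
          else if (bxn < 0 || bxn >= g.nbx) continue;
          for (int j = g.head[(size_t)byn * g.nbx + bxn]; j != -1; j = g.nxt[j]) {
            if (j <= i) continue;
            double dx = x[i] - x[j];
            if (periodic_x) dx -= width * std::round(dx / width);
            double dy = y[i] - y[j];
            double ov = (r[i] + r[j]) - std::sqrt(dx * dx + dy * dy);
            if (ov > resid) resid = ov;
          }
        }
      }
    }
    return resid;
  };

  double resid = 0.0;
  bool have_resid = false;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    have_resid = false;
    // bounding box (open domains drift); periodic x fixed to [0, width)
    double ymin = y[0], ymax = y[0], xmin = x[0], xmax = x[0];
    for (int i = 0; i < n; ++i) {
      if (y[i] < ymin) ymin = y[i]; if (y[i] > ymax) ymax = y[i];
      if (x[i] < xmin) xmin = x[i]; if (x[i] > xmax) xmax = x[i];
    }
    if (periodic_x) { g.x0 = 0.0; g.nbx = std::max(1, (int)std::floor(width / g.bin)); g.bin = width / g.nbx; }
    else { g.x0 = xmin - g.bin; g.nbx = std::max(1, (int)std::ceil((xmax - xmin + 2 * g.bin) / g.bin)); }
    g.y0 = ymin - g.bin;
    g.nby = std::max(1, (int)std::ceil((ymax - ymin + 2 * g.bin) / g.bin));
    g.build(x, y);

    // Fisher-Yates shuffle of sweep order
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xs32(rng) % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }

    max_ov = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int bxi = g.bx(x[i]), byi = g.by(y[i]);
      for (int dby = -1; dby <= 1; ++dby) {
        int byn = byi + dby;
        if (byn < 0 || byn >= g.nby) continue;
        for (int dbx = -1; dbx <= 1; ++dbx) {
          int bxn = bxi + dbx;
          if (g.wrap) { bxn %= g.nbx; if (bxn < 0) bxn += g.nbx; }
          else if (bxn < 0 || bxn >= g.nbx) continue;
          for (int j = g.head[(size_t)byn * g.nbx + bxn]; j != -1; j = g.nxt[j]) {
            if (j == i) continue;
            double dx = x[i] - x[j];
            if (periodic_x) dx -= width * std::round(dx / width);
            double dy = y[i] - y[j];
            double sumr = r[i] + r[j];
            double d2 = dx * dx + dy * dy;
            if (d2 >= sumr * sumr) continue;
            double d = std::sqrt(d2);
            double ov = sumr - d;
            if (ov > max_ov) max_ov = ov;
            double ux, uy;
            if (d < 1e-9) {  // coincident centres: random push axis
              double a = 2.0 * M_PI * (xs32(rng) / 4294967296.0);
              ux = std::cos(a); uy = std::sin(a); d = 0.0;
            } else { ux = dx / d; uy = dy / d; }
            double half = 0.5 * ov;
            x[i] += ux * half; y[i] += uy * half;
            x[j] -= ux * half; y[j] -= uy * half;
            if (floor_y) {  // project back onto the floor: reflection would
                            // cancel the push for exactly vertical pairs
              if (y[i] < r[i]) y[i] = r[i];
              if (y[j] < r[j]) y[j] = r[j];
            }
            if (periodic_x) {
              x[i] -= width * std::floor(x[i] / width);
              x[j] -= width * std::floor(x[j] / width);
            }
          }
        }
      }
    }
    // the per-sweep max tracks overlaps as encountered; resolving a pair can
    // push cells into fresh contacts, so confirm with a clean scan
    if (max_ov < tol) {
      resid = residual_scan();
      have_resid = true;
      if (resid < tol) { converged = true; ++sweep; break; }
    }
  }

  if (!have_resid) resid = residual_scan();
  converged = resid < tol;

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["sweeps"] = sweep,
                      _["max_overlap"] = resid,
                      _["converged"] = converged);
}
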