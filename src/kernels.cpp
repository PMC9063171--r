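#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom cubic convolution kernel (a = -0.5), support [-2, 2].
static inline double cubic_weight(double t) {
  const double a = -0.5;
  double at = std::fabs(t);
  if (at <= 1.0) return ((a + 2.0) * at - (a + 3.0)) * at * at + 1.0;
  if (at < 2.0)  return (((at - 5.0) * at + 8.0) * at - 4.0) * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable bicubic upscale by an integer factor with center-aligned sampling:
// source position of output index i is (i + 0.5)/factor - 0.5. Border samples
// are clamped; the result is clipped to [lo, hi].
// [[Rcpp::export]]
NumericMatrix bicubic_upscale_cpp(const NumericMatrix& x, int factor,
                                  double lo, double hi) {
  const int h = x.nrow(), w = x.ncol();
  const int oh = h * factor, ow = w * factor;

  // Per-phase tap weights and base offsets repeat with period `factor`.
  std::vector<double> wt(factor * 4);
  std::vector<int> base(factor);
  for (int p = 0; p < factor; ++p) {
    double s = (p + 0.5) / factor - 0.5;
    int i0 = (int)std::floor(s);
    base[p] = i0 - 1;
    for (int k = 0; k < 4; ++k)
      wt[p * 4 + k] = cubic_weight(s - (i0 - 1 + k));
  }

  // Pass 1: expand rows (h -> oh), columns unchanged. Runs of equal taps
  // (flat image areas) are passed through untouched so constant regions
  // stay bit-exact despite floating-point weight sums.
  NumericMatrix tmp(oh, w);
  for (int c = 0; c < w; ++c) {
    const double* col = &x(0, c);
    double* out = &tmp(0, c);
    for (int i = 0; i < oh; ++i) {
      int p = i % factor, ib = i / factor + base[p];
      double v0 = col[clampi(ib, 0, h - 1)], v1 = col[clampi(ib + 1, 0, h - 1)],
             v2 = col[clampi(ib + 2, 0, h - 1)], v3 = col[clampi(ib + 3, 0, h - 1)];
      if (v0 == v1 && v1 == v2 && v2 == v3) { out[i] = v0; continue; }
      out[i] = wt[p * 4] * v0 + wt[p * 4 + 1] * v1 +
               wt[p * 4 + 2] * v2 + wt[p * 4 + 3] * v3;
    }
  }

  // Pass 2: expand columns (w -> ow).
  NumericMatrix res(oh, ow);
  for (int j = 0; j < ow; ++j) {
    int p = j % factor, jb = j / factor + base[p];
    int c0 = clampi(jb, 0, w - 1), c1 = clampi(jb + 1, 0, w - 1),
        c2 = clampi(jb + 2, 0, w - 1), c3 = clampi(jb + 3, 0, w - 1);
    const double w0 = wt[p * 4], w1 = wt[p * 4 + 1],
                 w2 = wt[p * 4 + 2], w3 = wt[p * 4 + 3];
    const double *a = &tmp(0, c0), *b = &tmp(0, c1),
                 *c = &tmp(0, c2), *d = &tmp(0, c3);
    double* out = &res(0, j);
    for (int i = 0; i < oh; ++i) {
      double v;
      if (a[i] == b[i] && b[i] == c[i] && c[i] == d[i]) v = a[i];
      else v = w0 * a[i] + w1 * b[i] + w2 * c[i] + w3 * d[i];
      out[i] = v < lo ? lo : (v > hi ? hi : v);
    }
  }
  return res;
}

// Connected-component labelling of a logical mask. Components are labelled
// 1..N in raster-scan (row-major) order of their first pixel; connectivity is
// 4 or 8. Iterative BFS so deep regions cannot overflow the call stack.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;

  std::vector<int> queue;
  int next = 0;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      queue.clear();
      queue.push_back(r + c * h);
      while (!queue.empty()) {
        int idx = queue.back();
        queue.pop_back();
        int cr = idx % h, cc = idx / h;
        for (int k = 0; k < nn; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            queue.push_back(nr + nc * h);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing with Jacob's stopping criterion.
// Traces the outer boundary of the single 8-connected region in `mask`,
// clockwise in image coordinates (rows increase downward), starting from the
// first foreground pixel in raster-scan order (the top-left boundary pixel).
// Returns a k x 2 matrix of 1-based (row, col) boundary pixel coordinates.
// [[Rcpp::export]]
IntegerMatrix moore_trace_cpp(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < h && sr < 0; ++r)
    for (int c = 0; c < w; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);

  // Clockwise Moore neighbourhood starting due west.
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto inside = [&](int r, int c) {
    return r >= 0 && r < h && c >= 0 && c < w && mask(r, c);
  };

  std::vector<int> rows, cols;
  rows.push_back(sr + 1);
  cols.push_back(sc + 1);

  int cr = sr, cc = sc;
  // `back` indexes the background neighbour from which the sweep restarts;
  // the west neighbour of the raster-scan start pixel is always background.
  int back = 0;
  int first_dir = -1;  // direction of the first move, for Jacob's criterion
  const long maxit = 4L * h * w + 8;
  for (long it = 0; it < maxit; ++it) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (back + k) % 8;
      if (inside(cr + dr[d], cc + dc[d])) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    if (first_dir < 0) {
      first_dir = found;
    } else if (cr == sr && cc == sc && found == first_dir) {
      break;  // re-entered the start pixel leaving in the original direction
    }
    // Background neighbour examined immediately before the hit.
    int dp = (found + 7) % 8;
    int br = cr + dr[dp], bc = cc + dc[dp];
    cr += dr[found]; cc += dc[found];
    rows.push_back(cr + 1);
    cols.push_back(cc + 1);
    back = 0;
    for (int j = 0; j < 8; ++j)
      if (cr + dr[j] == br && cc + dc[j] == bc) { back = j; break; }
  }
  // Drop the final re-visit of the start pixel so the chain is a simple cycle.
  if (rows.size() > 1 && rows.back() == rows.front() && cols.back() == cols.front()) {
    rows.pop_back();
    cols.pop_back();
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}
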