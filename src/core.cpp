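#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 8-connected component labelling of a binary image (iterative flood fill).
// Returns integer matrix of labels, 0 = background, components numbered from 1
// in raster-scan order of their first pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (img(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb-Huttenlocher 1-D squared-distance transform.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean squared distance (in pixels) from every pixel to the nearest
// TRUE pixel. All-FALSE input returns +Inf everywhere.
// [[Rcpp::export(name = ".dist_transform_sq")]]
NumericMatrix dist_transform_sq(const LogicalMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double INF = std::numeric_limits<double>::infinity();
  // columns first
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // dt1d needs finite inputs: stand in a huge finite value for "no seed"
  // and map anything that large back to Inf at the end
  const double BIG = 1e15;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = img(r, c) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = (d[c] >= BIG) ? INF : d[c];
  }
  return out;
}

// Per-pixel median of a stack of equally sized numeric matrices.
// [[Rcpp::export(name = ".stack_median")]]
NumericMatrix stack_median(const List& frames) {
  int n = frames.size();
  if (n == 0) stop("empty stack");
  NumericMatrix f0 = frames[0];
  int nr = f0.nrow(), nc = f0.ncol();
  NumericMatrix out(nr, nc);
  std::vector<const double*> ptr(n);
  std::vector<NumericMatrix> keep;
  keep.reserve(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix fi = frames[i];
    if (fi.nrow() != nr || fi.ncol() != nc) stop("non-uniform frame shapes");
    keep.push_back(fi);
    ptr[i] = &keep[i][0];
  }
  std::vector<double> buf(n);
  int npx = nr * nc;
  for (int p = 0; p < npx; ++p) {
    for (int i = 0; i < n; ++i) buf[i] = ptr[i][p];
    std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
    double m = buf[n / 2];
    if (n % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
      m = 0.5 * (m + buf[n / 2 - 1]);
    }
    out[p] = m;
  }
  return out;
}

// Stamp a constant-width tube (round caps) around a polyline onto img
// (modified copy returned). Coordinates are 1-based (row, col) pixel centres;
// every pixel whose centre lies within `radius` of the polyline is set to
// `value`.
// [[Rcpp::export(name = ".stamp_tube")]]
NumericMatrix stamp_tube(const NumericMatrix& img, const NumericVector& row,
                         const NumericVector& col, double radius, double value) {
  NumericMatrix out = clone(img);
  int nr = out.nrow(), nc = out.ncol();
  int n = row.size();
  if (n == 0) return out;
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    double pr = row[i] - 1.0, pc = col[i] - 1.0; // 0-based centres
    if (i > 0) {
      // stamp along the segment from previous point at <=0.5 px spacing
      double qr = row[i - 1] - 1.0, qc = col[i - 1] - 1.0;
      double dr = pr - qr, dc = pc - qc;
      double len = std::sqrt(dr * dr + dc * dc);
      int nseg = (int)std::ceil(len / 0.5);
      for (int s = 1; s < nseg; ++s) {
        double t = (double)s / nseg;
        double mr = qr + t * dr, mc = qc + t * dc;
        int rlo = std::max(0, (int)std::floor(mr - radius));
        int rhi = std::min(nr - 1, (int)std::ceil(mr + radius));
        int clo = std::max(0, (int)std::floor(mc - radius));
        int chi = std::min(nc - 1, (int)std::ceil(mc + radius));
        for (int c = clo; c <= chi; ++c)
          for (int r = rlo; r <= rhi; ++r) {
            double dx = r - mr, dy = c - mc;
            if (dx * dx + dy * dy <= r2) out(r, c) = value;
          }
      }
    }
    int rlo = std::max(0, (int)std::floor(pr - radius));
    int rhi = std::min(nr - 1, (int)std::ceil(pr + radius));
    int clo = std::max(0, (int)std::floor(pc - radius));
    int chi = std::min(nc - 1, (int)std::ceil(pc + radius));
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        double dx = r - pr, dy = c - pc;
        if (dx * dx + dy * dy <= r2) out(r, c) = value;
      }
  }
  return out;
}

// Separable Gaussian blur, reflected boundaries, kernel truncated at 4 sigma.
// [[Rcpp::export(name = ".gaussian_blur")]]
NumericMatrix gaussian_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int hw = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * hw + 1);
  double s = 0;
  for (int i = -hw; i <= hw; ++i) {
    k[i + hw] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + hw];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -hw; i <= hw; ++i) acc += k[i + hw] * img(reflect(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -hw; i <= hw; ++i) acc += k[i + hw] * tmp(r, reflect(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Add Gaussian noise (R RNG) and quantize to 8-bit integers in one pass.
// [[Rcpp::export(name = ".noise_quantize")]]
IntegerMatrix noise_quantize(const NumericMatrix& img, double sd) {
  int n = img.size();
  IntegerMatrix out(img.nrow(), img.ncol());
  if (sd > 0) {
    RNGScope scope;
    for (int i = 0; i < n; ++i) {
      double v = std::round(img[i] + R::rnorm(0.0, sd));
      out[i] = (int)std::min(255.0, std::max(0.0, v));
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double v = std::round(img[i]);
      out[i] = (int)std::min(255.0, std::max(0.0, v));
    }
  }
  return out;
}

// |a - b| plus its 256-bin histogram in a single pass.
// [[Rcpp::export(name = ".abs_diff_hist")]]
List abs_diff_hist(const IntegerMatrix& a, const IntegerMatrix& b) {
  int n = a.size();
  IntegerMatrix d(a.nrow(), a.ncol());
  IntegerVector h(256);
  for (int i = 0; i < n; ++i) {
    int v = a[i] - b[i];
    if (v < 0) v = -v;
    d[i] = v;
    if (v > 255) v = 255;
    ++h[v];
  }
  return List::create(_["d"] = d, _["hist"] = h);
}
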