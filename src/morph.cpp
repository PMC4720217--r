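#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform of a 3-D grid, Felzenszwalb &
// Huttenlocher separable lower-envelope algorithm. Distances are to the
// nearest TRUE voxel, in voxel units; voxels with no TRUE anywhere get Inf.
// Arrays are column-major with dim = (d1, d2, d3) as in R.

// "No site" is a large finite sentinel so the lower envelope needs no special
// cases; anything >= LARGE/2 in the output means unreachable.
static const double LARGE = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : LARGE;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)k * d1 * d2 + (R_xlen_t)j * d1;
      bool any = false;
      for (int i = 0; i < d1; ++i) { f[i] = out[base + i]; if (f[i] == 0.0) any = true; }
      if (!any) continue;
      dt1d(f, dbuf, v, z, d1);
      for (int i = 0; i < d1; ++i) out[base + i] = dbuf[i];
    }
  // axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)k * d1 * d2 + i;
      for (int j = 0; j < d2; ++j) f[j] = out[base + (R_xlen_t)j * d1];
      dt1d(f, dbuf, v, z, d2);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)j * d1] = dbuf[j];
    }
  // axis 3
  const R_xlen_t stride3 = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)j * d1 + i;
      for (int k = 0; k < d3; ++k) f[k] = out[base + (R_xlen_t)k * stride3];
      dt1d(f, dbuf, v, z, d3);
      for (int k = 0; k < d3; ++k) out[base + (R_xlen_t)k * stride3] = dbuf[k];
    }
  // clamp unreachable to Inf for a clean contract
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= LARGE / 2) out[i] = std::numeric_limits<double>::infinity();
  return out;
}

// Connected-component labeling with 6- or 26-connectivity. Labels are
// assigned in raster order of each component's first voxel, so the result is
// deterministic. Returns integer vector (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<int> off1, off2, off3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && man != 1) continue;
        off1.push_back(a); off2.push_back(b); off3.push_back(c);
      }
  const int noff = (int)off1.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < noff; ++t) {
        int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
        R_xlen_t q = (R_xlen_t)kk * d1 * d2 + (R_xlen_t)jj * d1 + ii;
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Per-window depth histograms for the adaptive contraction. `level` holds,
// for each voxel of the expanded volume, the largest integer depth d >= 1
// with d^2 < squared-distance-to-background (clamped to rmax), and -1 for
// voxels outside the expanded volume. For each cubic window (center +/- half)
// the function returns cumulative counts tot[w, d+1] = |C_d /\ W| and
// org[w, d+1] = |C_d /\ O /\ W| for d = 0..rmax, plus the number of window
// voxels at level 0 (window-surface indicator).
// [[Rcpp::export]]
List cpp_window_counts(IntegerVector level, LogicalVector inO, IntegerVector dim,
                       IntegerVector c1, IntegerVector c2, IntegerVector c3,
                       int half, int rmax) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int nw = c1.size();
  IntegerMatrix tot(nw, rmax + 1), org(nw, rmax + 1);
  IntegerVector nsurf(nw);
  std::vector<int> hist(rmax + 1), histO(rmax + 1);
  for (int w = 0; w < nw; ++w) {
    std::fill(hist.begin(), hist.end(), 0);
    std::fill(histO.begin(), histO.end(), 0);
    int i0 = std::max(0, c1[w] - half), i1 = std::min(d1 - 1, c1[w] + half);
    int j0 = std::max(0, c2[w] - half), j1 = std::min(d2 - 1, c2[w] + half);
    int k0 = std::max(0, c3[w] - half), k1 = std::min(d3 - 1, c3[w] + half);
    int surf = 0;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        R_xlen_t base = (R_xlen_t)k * d1 * d2 + (R_xlen_t)j * d1;
        for (int i = i0; i <= i1; ++i) {
          int l = level[base + i];
          if (l < 0) continue;
          if (l == 0) ++surf;
          if (l > rmax) l = rmax;
          ++hist[l];
          if (inO[base + i]) ++histO[l];
        }
      }
    nsurf[w] = surf;
    // tot[, d] for d >= 1 is the suffix sum over levels >= d; d = 0 counts all
    int acc = 0, accO = 0;
    for (int l = rmax; l >= 1; --l) {
      acc += hist[l]; accO += histO[l];
      tot(w, l) = acc; org(w, l) = accO;
    }
    tot(w, 0) = acc + hist[0];
    org(w, 0) = accO + histO[0];
  }
  return List::create(_["tot"] = tot, _["orig"] = org, _["n_surface"] = nsurf);
}

// Trilinear interpolation of a regular-grid field at voxel coordinates.
// Grid node g (1-based index gi along axis a) sits at coordinate
// origin[a] + (gi-1)*spacing[a]; query points outside the hull are clamped.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector grid, IntegerVector gdim,
                            NumericVector origin, NumericVector spacing,
                            NumericVector p1, NumericVector p2, NumericVector p3) {
  const int g1 = gdim[0], g2 = gdim[1], g3 = gdim[2];
  const R_xlen_t np = p1.size();
  NumericVector out(np);
  for (R_xlen_t q = 0; q < np; ++q) {
    double x = (p1[q] - origin[0]) / spacing[0];
    double y = (p2[q] - origin[1]) / spacing[1];
    double z = (p3[q] - origin[2]) / spacing[2];
    if (x < 0) x = 0; if (x > g1 - 1) x = g1 - 1;
    if (y < 0) y = 0; if (y > g2 - 1) y = g2 - 1;
    if (z < 0) z = 0; if (z > g3 - 1) z = g3 - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > g1 - 2) x0 = std::max(0, g1 - 2);
    if (y0 > g2 - 2) y0 = std::max(0, g2 - 2);
    if (z0 > g3 - 2) z0 = std::max(0, g3 - 2);
    int x1 = std::min(x0 + 1, g1 - 1), y1 = std::min(y0 + 1, g2 - 1), z1 = std::min(z0 + 1, g3 - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    #define G(a,b,c) grid[(R_xlen_t)(c) * g1 * g2 + (R_xlen_t)(b) * g1 + (a)]
    double c00 = G(x0, y0, z0) * (1 - fx) + G(x1, y0, z0) * fx;
    double c10 = G(x0, y1, z0) * (1 - fx) + G(x1, y1, z0) * fx;
    double c01 = G(x0, y0, z1) * (1 - fx) + G(x1, y0, z1) * fx;
    double c11 = G(x0, y1, z1) * (1 - fx) + G(x1, y1, z1) * fx;
    #undef G
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[q] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
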