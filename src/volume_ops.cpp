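// 3D voxel-grid primitives used throughout the package.
// All arrays are R arrays with dim = c(nz, ny, nx); linear index
// i = z + nz * (y + ny * x), 0-based on the C++ side.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e20;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel centre. Background voxels get 0.
static void edt_sq(const LogicalVector& fg, int nz, int ny, int nx,
                   std::vector<double>& D) {
  size_t n = (size_t)nz * ny * nx;
  D.resize(n);
  for (size_t i = 0; i < n; ++i) D[i] = fg[i] ? BIG : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nz * (y + (size_t)ny * x);
      for (int zz = 0; zz < nz; ++zz) f[zz] = D[base + zz];
      dt1d(f, d, nz, v, z);
      for (int zz = 0; zz < nz; ++zz) D[base + zz] = d[zz];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      size_t base = zz + (size_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (size_t)nz * y];
      dt1d(f, d, ny, v, z);
      for (int y = 0; y < ny; ++y) D[base + (size_t)nz * y] = d[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      size_t base = zz + (size_t)nz * y;
      size_t stride = (size_t)nz * ny;
      for (int x = 0; x < nx; ++x) f[x] = D[base + stride * x];
      dt1d(f, d, nx, v, z);
      for (int x = 0; x < nx; ++x) D[base + stride * x] = d[x];
    }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> D;
  edt_sq(fg, nz, ny, nx, D);
  NumericVector out(D.size());
  for (size_t i = 0; i < D.size(); ++i) out[i] = std::sqrt(D[i]);
  return out;
}

// Connected-component labelling (6 or 26 connectivity), labels in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector fg, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  int nn = (int)dz.size();
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!fg[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur / ((size_t)nz * ny));
      int rem = (int)(cur % ((size_t)nz * ny));
      int y = rem / nz, zz = rem % nz;
      for (int k = 0; k < nn; ++k) {
        int z2 = zz + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
        if (fg[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Fill internal holes: background components not connected (6-conn) to the
// array border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector fg, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<char> reached(n, 0);
  std::vector<size_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz) {
        if (zz != 0 && zz != nz - 1 && y != 0 && y != ny - 1 && x != 0 &&
            x != nx - 1)
          continue;
        size_t i = zz + (size_t)nz * (y + (size_t)ny * x);
        if (!fg[i] && !reached[i]) {
          reached[i] = 1;
          stack.push_back(i);
        }
      }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t cur = stack.back();
    stack.pop_back();
    int x = (int)(cur / ((size_t)nz * ny));
    int rem = (int)(cur % ((size_t)nz * ny));
    int y = rem / nz, zz = rem % nz;
    for (int k = 0; k < 6; ++k) {
      int z2 = zz + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
      if (!fg[j] && !reached[j]) {
        reached[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = fg[i] || !reached[i];
  return out;
}

// Separable mean filter with window half-width r along each axis,
// edge-normalised by the actual in-bounds window size.
static void blur_axis(std::vector<double>& a, int nz, int ny, int nx, int axis,
                      int r) {
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nz : (size_t)nz * ny);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  std::vector<double> line(len), cum(len + 1);
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      size_t base;
      if (axis == 0) base = (size_t)nz * (i1 + (size_t)ny * i2);
      else if (axis == 1) base = i1 + (size_t)nz * ny * i2;
      else base = i1 + (size_t)nz * i2;
      cum[0] = 0.0;
      for (int t = 0; t < len; ++t) cum[t + 1] = cum[t] + a[base + stride * t];
      for (int t = 0; t < len; ++t) {
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        a[base + stride * t] = (cum[hi + 1] - cum[lo]) / (hi - lo + 1);
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_box_blur(NumericVector arr, IntegerVector dims, int r) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> a(arr.begin(), arr.end());
  if (r > 0) {
    blur_axis(a, nz, ny, nx, 0, r);
    blur_axis(a, nz, ny, nx, 1, r);
    blur_axis(a, nz, ny, nx, 2, r);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// Local maxima of `val` over the 26-neighbourhood, restricted to fg and
// val >= min_value; then greedy suppression so accepted peaks are at least
// min_dist (voxels) apart, visiting candidates in decreasing value
// (ties: increasing linear index). Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_peak_markers(NumericVector val, LogicalVector fg,
                               IntegerVector dims, double min_dist,
                               double min_value) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<size_t> cand;
  for (size_t i = 0; i < n; ++i) {
    if (!fg[i] || val[i] < min_value) continue;
    int x = (int)(i / ((size_t)nz * ny));
    int rem = (int)(i % ((size_t)nz * ny));
    int y = rem / nz, zz = rem % nz;
    bool ok = true;
    for (int a = -1; a <= 1 && ok; ++a)
      for (int b = -1; b <= 1 && ok; ++b)
        for (int c = -1; c <= 1 && ok; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          int z2 = zz + a, y2 = y + b, x2 = x + c;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
          if (val[j] > val[i]) ok = false;
        }
    if (ok) cand.push_back(i);
  }
  std::sort(cand.begin(), cand.end(), [&](size_t a, size_t b) {
    if (val[a] != val[b]) return val[a] > val[b];
    return a < b;
  });
  std::vector<size_t> acc;
  std::vector<double> az, ay, ax;
  double md2 = min_dist * min_dist;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    size_t i = cand[ci];
    int x = (int)(i / ((size_t)nz * ny));
    int rem = (int)(i % ((size_t)nz * ny));
    int y = rem / nz, zz = rem % nz;
    bool ok = true;
    for (size_t k = 0; k < acc.size(); ++k) {
      double dzv = zz - az[k], dyv = y - ay[k], dxv = x - ax[k];
      if (dzv * dzv + dyv * dyv + dxv * dxv < md2) { ok = false; break; }
    }
    if (ok) {
      acc.push_back(i);
      az.push_back(zz); ay.push_back(y); ax.push_back(x);
    }
  }
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = (int)(acc[k] + 1);
  return out;
}

// Marker-based watershed by priority flood: regions grow from markers in
// decreasing order of `priority` (ties: smallest linear index first),
// 6-connected, restricted to fg. Deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector fg,
                            IntegerVector markers, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  typedef std::pair<double, long long> Node; // (priority, -index)
  std::priority_queue<Node> heap;
  for (size_t i = 0; i < n; ++i) {
    if (markers[i] > 0) {
      lab[i] = markers[i];
      heap.push(Node(priority[i], -(long long)i));
    }
  }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!heap.empty()) {
    Node nd = heap.top();
    heap.pop();
    size_t cur = (size_t)(-nd.second);
    int x = (int)(cur / ((size_t)nz * ny));
    int rem = (int)(cur % ((size_t)nz * ny));
    int y = rem / nz, zz = rem % nz;
    for (int k = 0; k < 6; ++k) {
      int z2 = zz + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
      if (fg[j] && lab[j] == 0) {
        lab[j] = lab[cur];
        heap.push(Node(priority[j], -(long long)j));
      }
    }
  }
  return lab;
}

// Local thickness by maximal inscribed spheres: every foreground voxel q
// carries a sphere of radius r(q) = EDT(q) - 0.5 (centre-to-boundary
// distance); each voxel p covered by a sphere records twice the largest
// covering radius. `slack` widens the coverage test to compensate for
// sampling spheres only at voxel centres.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dims,
                                  double slack) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> D;
  edt_sq(fg, nz, ny, nx, D);
  std::vector<double> r(n, 0.0);
  std::vector<size_t> idx;
  for (size_t i = 0; i < n; ++i) {
    if (fg[i]) {
      r[i] = std::sqrt(D[i]) - 0.5;
      if (r[i] < 0) r[i] = 0;
      idx.push_back(i);
    }
  }
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return r[a] > r[b]; });
  NumericVector th(n, 0.0);
  for (size_t k = 0; k < idx.size(); ++k) {
    size_t q = idx[k];
    double rq = r[q], reach = rq + slack;
    int R = (int)std::floor(reach);
    double reach2 = reach * reach, val = 2.0 * rq;
    int x = (int)(q / ((size_t)nz * ny));
    int rem = (int)(q % ((size_t)nz * ny));
    int y = rem / nz, zz = rem % nz;
    for (int a = std::max(0, zz - R); a <= std::min(nz - 1, zz + R); ++a) {
      double da = (double)(a - zz) * (a - zz);
      for (int b = std::max(0, y - R); b <= std::min(ny - 1, y + R); ++b) {
        double db = (double)(b - y) * (b - y);
        if (da + db > reach2) continue;
        for (int c = std::max(0, x - R); c <= std::min(nx - 1, x + R); ++c) {
          double dc = (double)(c - x) * (c - x);
          if (da + db + dc > reach2) continue;
          size_t j = a + (size_t)nz * (b + (size_t)ny * c);
          if (fg[j] && th[j] < val) th[j] = val;
        }
      }
    }
  }
  return th;
}

// Signed first-order distance (mm, positive inside) to the seed surface
// rad_scaled = g(t) with g(t) = sqrt(1-t^2) * (1 - pinch*t^2) *
// (1 - taper*(1+t)/2), evaluated on the voxel grid defined by the axis
// coordinate vectors gz/gy/gx (mm, seed-centred) and rotation R (columns =
// local axes in world z,y,x components).
// [[Rcpp::export]]
NumericVector cpp_spindle_dist(NumericVector gz, NumericVector gy,
                               NumericVector gx, NumericMatrix R,
                               double a, double b, double c,
                               double pinch, double taper) {
  int nz = gz.size(), ny = gy.size(), nx = gx.size();
  size_t n = (size_t)nz * ny * nx;
  NumericVector out(n);
  double R11 = R(0, 0), R21 = R(1, 0), R31 = R(2, 0);
  double R12 = R(0, 1), R22 = R(1, 1), R32 = R(2, 1);
  double R13 = R(0, 2), R23 = R(1, 2), R33 = R(2, 2);
  size_t i = 0;
  for (int x = 0; x < nx; ++x) {
    double wx = gx[x];
    for (int y = 0; y < ny; ++y) {
      double wy = gy[y];
      for (int z = 0; z < nz; ++z, ++i) {
        double wz = gz[z];
        double l1 = R11 * wz + R21 * wy + R31 * wx;
        double l2 = R12 * wz + R22 * wy + R32 * wx;
        double l3 = R13 * wz + R23 * wy + R33 * wx;
        double t = l1 / a;
        if (t > 1.0 || t < -1.0) {
          double sgn = t > 0 ? 1.0 : -1.0;
          double dz1 = l1 - sgn * a;
          out[i] = -std::sqrt(dz1 * dz1 + l2 * l2 + l3 * l3);
          continue;
        }
        double u = 1.0 - t * t;
        double su = std::sqrt(u);
        double pin = 1.0 - pinch * t * t;
        double tap = 1.0 - taper * (1.0 + t) / 2.0;
        double g = su * pin * tap;
        // dg/dt
        double dsu = (su > 1e-8) ? (-t / su) : (t > 0 ? -1e8 : 1e8);
        double dg = dsu * pin * tap + su * (-2.0 * pinch * t) * tap +
          su * pin * (-taper / 2.0);
        double y2 = l2 / b, z2v = l3 / c;
        double rad = std::sqrt(y2 * y2 + z2v * z2v);
        double grad2;
        if (rad > 1e-12) {
          double gy2 = l2 / (b * b), gz2 = l3 / (c * c);
          grad2 = (gy2 * gy2 + gz2 * gz2) / (rad * rad);
        } else {
          grad2 = 1.0 / (b * c);
        }
        double gr = std::sqrt((dg / a) * (dg / a) + grad2);
        if (gr < 1e-9) gr = 1e-9;
        out[i] = (g - rad) / gr;
      }
    }
  }
  return out;
}

// Squared distance (mm^2) of every voxel to a reference point.
// [[Rcpp::export]]
NumericVector cpp_dist2_point(NumericVector gz, NumericVector gy,
                              NumericVector gx, NumericVector p) {
  int nz = gz.size(), ny = gy.size(), nx = gx.size();
  size_t n = (size_t)nz * ny * nx;
  NumericVector out(n);
  size_t i = 0;
  for (int x = 0; x < nx; ++x) {
    double dx = gx[x] - p[2];
    for (int y = 0; y < ny; ++y) {
      double dy = gy[y] - p[1];
      double dxy = dx * dx + dy * dy;
      for (int z = 0; z < nz; ++z, ++i) {
        double dz = gz[z] - p[0];
        out[i] = dxy + dz * dz;
      }
    }
  }
  return out;
}

// Bisection on the cavity-cap radius: find R so that the fraction of seed
// voxels that stay kernel (inner & dist2 >= R^2) hits the target fullness.
// [[Rcpp::export]]
double cpp_fullness_bisect(NumericVector dist2, LogicalVector inner,
                           double n_seed, double target, double lo,
                           double hi, double tol, int iters) {
  size_t n = dist2.size();
  double R = 0.0;
  for (int it = 0; it < iters; ++it) {
    R = 0.5 * (lo + hi);
    double R2 = R * R;
    size_t cnt = 0;
    for (size_t i = 0; i < n; ++i)
      if (inner[i] && dist2[i] >= R2) ++cnt;
    double f = cnt / n_seed;
    if (std::fabs(f - target) <= tol) break;
    if (f > target) lo = R; else hi = R;
  }
  return R;
}

// Assemble the phantom phase fields in one pass: fractional occupancies
// from the outer signed distance dn (mm), the coat inner surface at depth
// ct, and the cavity cap of radius Rcap around the pole point (dist2 in
// mm^2); returns the noise-free intensity contribution and the binary
// component masks.
// [[Rcpp::export]]
List cpp_render_phases(NumericVector dn, NumericVector dist2, double sp,
                       double ct, double Rcap, double icoat, double ikern,
                       double icav) {
  size_t n = dn.size();
  NumericVector contrib(n);
  LogicalVector seed(n), kernel(n), coat(n), cavity(n);
  double nseed = 0, nkern = 0, ncoat = 0, ncav = 0;
  for (size_t i = 0; i < n; ++i) {
    double O = 0.5 + dn[i] / sp;
    if (O <= 0) { continue; }
    if (O > 1) O = 1;
    double oin = 0.5 + (dn[i] - ct) / sp;
    if (oin < 0) oin = 0; else if (oin > 1) oin = 1;
    double cap = 0.0;
    if (Rcap > 0) {
      cap = 0.5 + (Rcap - std::sqrt(dist2[i])) / sp;
      if (cap < 0) cap = 0; else if (cap > 1) cap = 1;
    }
    double cf = O - oin; if (cf < 0) cf = 0;
    double kf = oin * (1 - cap), vf = oin * cap;
    contrib[i] = cf * icoat + kf * ikern + vf * icav;
    bool s = O >= 0.5;
    seed[i] = s;
    if (s) {
      ++nseed;
      bool inn = dn[i] >= ct;
      if (inn) {
        bool cav = dist2[i] < Rcap * Rcap;
        cavity[i] = cav;
        kernel[i] = !cav;
        if (cav) ++ncav; else ++nkern;
      } else {
        coat[i] = true;
        ++ncoat;
      }
    }
  }
  return List::create(_["contrib"] = contrib, _["seed"] = seed,
                      _["kernel"] = kernel, _["coat"] = coat,
                      _["cavity"] = cavity,
                      _["counts"] = NumericVector::create(nseed, nkern,
                                                          ncoat, ncav));
}

// Face-connected (6-neighbourhood) binary erosion / dilation, radius 1.
// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector fg, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n);
  const int* p = LOGICAL(fg);
  int* q = LOGICAL(out);
  size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        bool v = p[i] != 0;
        if (v) {
          v = z > 0 && z < nz - 1 && y > 0 && y < ny - 1 && x > 0 &&
              x < nx - 1 && p[i - 1] && p[i + 1] && p[i - nz] && p[i + nz] &&
              p[i - (size_t)nz * ny] && p[i + (size_t)nz * ny];
        }
        q[i] = v;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate6(LogicalVector fg, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n);
  const int* p = LOGICAL(fg);
  int* q = LOGICAL(out);
  size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        bool v = p[i] != 0;
        if (!v) {
          v = (z > 0 && p[i - 1]) || (z < nz - 1 && p[i + 1]) ||
              (y > 0 && p[i - nz]) || (y < ny - 1 && p[i + nz]) ||
              (x > 0 && p[i - (size_t)nz * ny]) ||
              (x < nx - 1 && p[i + (size_t)nz * ny]);
        }
        q[i] = v;
      }
  return out;
}

// Bounding boxes (1-based, zlo,zhi,ylo,yhi,xlo,xhi per row) and sizes of
// positive labels in one pass.
// [[Rcpp::export]]
List cpp_label_boxes(IntegerVector lab, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int K = 0;
  size_t n = (size_t)nz * ny * nx;
  const int* p = INTEGER(lab);
  for (size_t i = 0; i < n; ++i) if (p[i] > K) K = p[i];
  IntegerMatrix box(K, 6);
  IntegerVector sizes(K);
  for (int k = 0; k < K; ++k) {
    box(k, 0) = nz; box(k, 1) = 0; box(k, 2) = ny;
    box(k, 3) = 0; box(k, 4) = nx; box(k, 5) = 0;
  }
  size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        int k = p[i] - 1;
        if (k < 0) continue;
        ++sizes[k];
        if (z + 1 < box(k, 0)) box(k, 0) = z + 1;
        if (z + 1 > box(k, 1)) box(k, 1) = z + 1;
        if (y + 1 < box(k, 2)) box(k, 2) = y + 1;
        if (y + 1 > box(k, 3)) box(k, 3) = y + 1;
        if (x + 1 < box(k, 4)) box(k, 4) = x + 1;
        if (x + 1 > box(k, 5)) box(k, 5) = x + 1;
      }
  return List::create(_["boxes"] = box, _["sizes"] = sizes);
}
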