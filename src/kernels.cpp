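// Low-level 3D image kernels. All volumes are R arrays in (z, y, x) order,
// i.e. column-major linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// finite sentinel for "no source yet": keeps the parabola intersections in
// dt1d finite (true infinities produce NaN envelopes on all-foreground
// columns); far above any real squared distance (nm^2) in a 3D stack
static const double HUGE_D = 1e20;

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with a
// physical grid spacing: d(p) = min_q f(q) + w2*(p-q)^2, w2 = spacing^2.
static void dt1d(std::vector<double>& f, double w2, int n,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Anisotropic Euclidean distance transform of a foreground mask:
// distance (in the units of `spacing`) from each foreground voxel to the
// nearest background voxel. dims = (nz, ny, nx); spacing = (sz, sy, sx).
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? HUGE_D : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = d[base + q];
      dt1d(f, sz * sz, nz, v, z, dd);
      for (int q = 0; q < nz; ++q) d[base + q] = dd[q];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = d[base + (R_xlen_t)nz * q];
      dt1d(f, sy * sy, ny, v, z, dd);
      for (int q = 0; q < ny; ++q) d[base + (R_xlen_t)nz * q] = dd[q];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * y;
      R_xlen_t stride = (R_xlen_t)nz * ny;
      for (int q = 0; q < nx; ++q) f[q] = d[base + stride * q];
      dt1d(f, sx * sx, nx, v, z, dd);
      for (int q = 0; q < nx; ++q) d[base + stride * q] = dd[q];
    }

  for (R_xlen_t i = 0; i < n; ++i) d[i] = std::sqrt(d[i]);
  return d;
}

struct QItem {
  double priority;
  unsigned long order;
  R_xlen_t idx;
  int label;
};
struct QCmp {
  // lowest relief first; FIFO on ties -> deterministic flooding
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding of `relief` (ascending) restricted to
// `mask`, 6-connected. seedIdx are 1-based linear indices into the volume.
// Returns an integer label volume (0 = background).
// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector relief, LogicalVector mask,
                              IntegerVector dims, NumericVector seedIdx,
                              IntegerVector seedLabel) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<bool> queued(n, false);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;

  for (R_xlen_t s = 0; s < seedIdx.size(); ++s) {
    R_xlen_t i = (R_xlen_t)seedIdx[s] - 1;
    if (i < 0 || i >= n || !mask[i])
      stop("seed outside the foreground mask");
    if (!queued[i]) {
      queued[i] = true;
      pq.push({relief[i], order++, i, seedLabel[s]});
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    if (labels[it.idx] != 0) continue;
    labels[it.idx] = it.label;
    int zi = (int)(it.idx % nz);
    R_xlen_t r = it.idx / nz;
    int yi = (int)(r % ny);
    int xi = (int)(r / ny);
    const int dz[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dx[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int z2 = zi + dz[k], y2 = yi + dy[k], x2 = xi + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (mask[j] && !queued[j] && labels[j] == 0) {
        queued[j] = true;
        pq.push({relief[j], order++, j, it.label});
      }
    }
  }
  return labels;
}

static void blur_axis(std::vector<double>& a, std::vector<double>& tmp,
                      const std::vector<double>& kern, int radius,
                      int len, R_xlen_t base, R_xlen_t stride) {
  // reflecting boundary
  for (int p = 0; p < len; ++p) {
    double acc = 0.0;
    for (int k = -radius; k <= radius; ++k) {
      int q = p + k;
      if (q < 0) q = -q - 1;
      if (q >= len) q = 2 * len - q - 1;
      acc += kern[k + radius] * a[base + stride * q];
    }
    tmp[p] = acc;
  }
  for (int p = 0; p < len; ++p) a[base + stride * p] = tmp[p];
}

// Separable anisotropic Gaussian blur; sigma in pixels per axis (z, y, x).
// sigma <= 0 on an axis skips that axis.
// [[Rcpp::export(name = ".gauss_blur3d_cpp")]]
NumericVector gauss_blur3d_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end());
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> tmp(nmax);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int radius = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * radius + 1);
    double sum = 0.0;
    for (int k = -radius; k <= radius; ++k) {
      kern[k + radius] = std::exp(-0.5 * k * k / (s * s));
      sum += kern[k + radius];
    }
    for (double& w : kern) w /= sum;

    if (axis == 0) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          blur_axis(a, tmp, kern, radius, nz,
                    (R_xlen_t)nz * (y + (R_xlen_t)ny * x), 1);
    } else if (axis == 1) {
      for (int x = 0; x < nx; ++x)
        for (int zi = 0; zi < nz; ++zi)
          blur_axis(a, tmp, kern, radius, ny,
                    zi + (R_xlen_t)nz * ny * x, nz);
    } else {
      for (int y = 0; y < ny; ++y)
        for (int zi = 0; zi < nz; ++zi)
          blur_axis(a, tmp, kern, radius, nx,
                    zi + (R_xlen_t)nz * y, (R_xlen_t)nz * ny);
    }
  }
  return NumericVector(a.begin(), a.end());
}

// 26-neighbourhood local maxima of v restricted to mask (plateaus included:
// a voxel is a maximum if no neighbour exceeds it). Returns 1-based indices.
// [[Rcpp::export(name = ".localmax3d_cpp")]]
IntegerVector localmax3d_cpp(NumericVector v, LogicalVector mask,
                             IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<R_xlen_t> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int zi = 0; zi < nz; ++zi) {
        R_xlen_t i = zi + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i] || v[i] <= 0) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int z2 = zi + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                  x2 < 0 || x2 >= nx)
                continue;
              R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
              if (v[j] > v[i]) ismax = false;
            }
        if (ismax) out.push_back(i + 1);
      }
  return IntegerVector(out.begin(), out.end());
}
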