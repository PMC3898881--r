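#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Trilinear sample of a 3-D volume at one continuous voxel coordinate
// (0-based). Outside the grid -> 0 (zero padding).
static inline double trilinear(const double *src, int nx, int ny, int nz,
                               double x, double y, double z,
                               bool *inside = nullptr) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
    if (inside) *inside = false;
    return 0.0;
  }
  if (inside) *inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * src[xx + nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector resample_coords_cpp(NumericVector src, IntegerVector sdim,
                                  NumericMatrix coords) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *s = src.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = trilinear(s, nx, ny, nz, coords(i, 0), coords(i, 1), coords(i, 2));
  return out;
}

// Resample src onto a grid of shape odim through a 3x4 voxel-to-voxel affine
// (rows map output voxel (i,j,k,1) to source voxel coordinates).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericMatrix M) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *s = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j) {
      double xj = m01 * j + m02 * k + m03;
      double yj = m11 * j + m12 * k + m13;
      double zj = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx)
        out[idx] = trilinear(s, nx, ny, nz,
                             m00 * i + xj, m10 * i + yj, m20 * i + zj);
    }
  return out;
}

// Mean squared intensity difference between `fixed` and `moving` resampled
// through the 3x4 voxel-to-voxel map M, over in-FOV fixed voxels (optionally
// restricted to mask != 0). Returns +large when the overlap is below half the
// (masked) fixed grid, so optimisers are pushed back toward overlap.
// [[Rcpp::export]]
double ssd_affine_cpp(NumericVector fixed, IntegerVector fdim,
                      NumericVector moving, IntegerVector mdim,
                      NumericMatrix M, IntegerVector mask, int stride = 1) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int ox = fdim[0], oy = fdim[1], oz = fdim[2];
  const double *mv = moving.begin();
  bool use_mask = mask.size() == fixed.size();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double acc = 0.0;
  R_xlen_t nvalid = 0, ntot = 0;
  for (int k = 0; k < oz; k += stride)
    for (int j = 0; j < oy; j += stride)
      for (int i = 0; i < ox; i += stride) {
        R_xlen_t idx = i + ox * (j + (R_xlen_t)oy * k);
        if (use_mask && mask[idx] == 0) continue;
        ++ntot;
        bool inside;
        double v = trilinear(mv, nx, ny, nz,
                             m00 * i + m01 * j + m02 * k + m03,
                             m10 * i + m11 * j + m12 * k + m13,
                             m20 * i + m21 * j + m22 * k + m23, &inside);
        if (!inside) continue;
        double d = v - fixed[idx];
        acc += d * d;
        ++nvalid;
      }
  if (ntot == 0 || nvalid < ntot / 2) return 1e30;
  return acc / nvalid;
}

// Negated mutual information (32-bin joint histogram) of fixed vs. resampled
// moving, same conventions as ssd_affine_cpp.
// [[Rcpp::export]]
double neg_mi_affine_cpp(NumericVector fixed, IntegerVector fdim,
                         NumericVector moving, IntegerVector mdim,
                         NumericMatrix M, IntegerVector mask, int nbins) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int ox = fdim[0], oy = fdim[1], oz = fdim[2];
  const double *mv = moving.begin();
  bool use_mask = mask.size() == fixed.size();
  double fmin = R_PosInf, fmax = R_NegInf, mmin = R_PosInf, mmax = R_NegInf;
  for (R_xlen_t i = 0; i < fixed.size(); ++i) {
    if (use_mask && mask[i] == 0) continue;
    fmin = std::min(fmin, fixed[i]); fmax = std::max(fmax, fixed[i]);
  }
  for (R_xlen_t i = 0; i < moving.size(); ++i) {
    mmin = std::min(mmin, moving[i]); mmax = std::max(mmax, moving[i]);
  }
  if (!(fmax > fmin) || !(mmax > mmin)) return 1e30;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t nvalid = 0, ntot = 0, idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        if (use_mask && mask[idx] == 0) continue;
        ++ntot;
        bool inside;
        double v = trilinear(mv, nx, ny, nz,
                             m00 * i + m01 * j + m02 * k + m03,
                             m10 * i + m11 * j + m12 * k + m13,
                             m20 * i + m21 * j + m22 * k + m23, &inside);
        if (!inside) continue;
        int bf = (int)((fixed[idx] - fmin) / (fmax - fmin) * (nbins - 1) + 0.5);
        int bm = (int)((v - mmin) / (mmax - mmin) * (nbins - 1) + 0.5);
        bf = std::min(std::max(bf, 0), nbins - 1);
        bm = std::min(std::max(bm, 0), nbins - 1);
        joint[bf + (size_t)nbins * bm] += 1.0;
        ++nvalid;
      }
  if (ntot == 0 || nvalid < ntot / 2) return 1e30;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int b = 0; b < nbins; ++b)
    for (int c = 0; c < nbins; ++c) {
      double p = joint[b + (size_t)nbins * c] / nvalid;
      joint[b + (size_t)nbins * c] = p;
      pf[b] += p; pm[c] += p;
    }
  double mi = 0.0;
  for (int b = 0; b < nbins; ++b)
    for (int c = 0; c < nbins; ++c) {
      double p = joint[b + (size_t)nbins * c];
      if (p > 0) mi += p * std::log(p / (pf[b] * pm[c]));
    }
  return -mi;
}

// Separable Gaussian blur with half-sample reflecting boundaries
// (mass-conserving for symmetric kernels). sigma per axis in voxels.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector src, IntegerVector dim,
                             NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(src.begin(), src.end()), b(n);
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(5.0 * s));
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + r];
    }
    for (double &x : w) x /= tot;
    int nax = dims[ax];
    R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? 1 : 0;
    int o2 = (ax == 2) ? 1 : 2;
    R_xlen_t st1 = strides[o1], st2 = strides[o2];
    int n1 = dims[o1], n2 = dims[o2];
    std::vector<double> line(nax + 2 * r);
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        R_xlen_t base = j1 * st1 + j2 * st2;
        for (int i = 0; i < nax; ++i) line[r + i] = a[base + i * st];
        for (int i = 0; i < r; ++i) {
          line[r - 1 - i] = line[r + std::min(i, nax - 1)];
          line[r + nax + i] = line[r + nax - 1 - std::min(i, nax - 1)];
        }
        for (int i = 0; i < nax; ++i) {
          double acc = 0;
          for (int t = 0; t <= 2 * r; ++t) acc += w[t] * line[i + t];
          b[base + i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

static void neighbour_offsets(int connectivity, std::vector<int> &di,
                              std::vector<int> &dj, std::vector<int> &dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && nz != 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Connected-component labels (1..L) of mask != 0; 0 elsewhere.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = ii + nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

struct UnionFind {
  std::vector<int> parent;
  std::vector<double> size;
  explicit UnionFind(R_xlen_t n) : parent(n, -1), size(n, 0.0) {}
  int find(int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Threshold-free cluster enhancement of the positive tail:
//   TFCE(v) = sum_{h = dh, 2dh, ... <= stat(v)} e(h,v)^E * h^H * dh
// with e(h,v) the voxel count of the suprathreshold component containing v.
// Descending threshold sweep with incremental union-find.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim,
                       double E, double H, double dh, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);
  double hmax = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) hmax = std::max(hmax, stat[i]);
  if (hmax <= 0 || dh <= 0) return out;
  int nsteps = (int)std::floor(hmax / dh + 1e-12);
  if (nsteps < 1) return out;
  std::vector<int> order;
  order.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) if (stat[i] >= dh) order.push_back((int)i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  UnionFind uf(n);
  std::vector<char> active(n, 0);
  size_t pos = 0;
  for (int s = nsteps; s >= 1; --s) {
    double h = s * dh;
    while (pos < order.size() && stat[order[pos]] >= h) {
      int v = order[pos++];
      uf.parent[v] = v;
      uf.size[v] = 1.0;
      active[v] = 1;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = ii + nx * (jj + (R_xlen_t)ny * kk);
        if (active[w]) uf.unite(v, (int)w);
      }
    }
    double hh = std::pow(h, H) * dh;
    for (size_t t = 0; t < pos; ++t) {
      int v = order[t];
      out[v] += std::pow(uf.size[uf.find(v)], E) * hh;
    }
  }
  return out;
}
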