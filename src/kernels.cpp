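#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// Connected-component labeling of a 3D logical array (dim ny, nx, nz).
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels start at 1,
// background stays 0. Iterative flood fill with an explicit stack.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() == 2) {
    IntegerVector d3 = IntegerVector::create(dims[0], dims[1], 1);
    dims = d3;
  }
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(n, 0);
  labels.attr("dim") = mask.attr("dim");

  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dy, dx, dz});
      }

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int iy = (int)(idx % ny);
      int ix = (int)((idx / ny) % nx);
      int iz = (int)(idx / ((R_xlen_t)ny * nx));
      for (size_t k = 0; k < offs.size(); ++k) {
        int jy = iy + offs[k][0], jx = ix + offs[k][1], jz = iz + offs[k][2];
        if (jy < 0 || jy >= ny || jx < 0 || jx >= nx || jz < 0 || jz >= nz)
          continue;
        R_xlen_t j = jy + (R_xlen_t)ny * (jx + (R_xlen_t)nx * jz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = current;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2] - u[2]*v[1];
  double w1 = u[2]*v[0] - u[0]*v[2];
  double w2 = u[0]*v[1] - u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// Total area of the iso-surface of a scalar field (dim ny, nx, nz) by
// marching tetrahedra: each grid cube is split into 6 tetrahedra sharing
// the main diagonal; crossing edges are interpolated linearly.
// Spacing (dy, dx, dz) is in physical units so the area is physical.
// [[Rcpp::export]]
double cpp_marching_area(NumericVector field, double iso,
                         double dy, double dx, double dz) {
  IntegerVector dims = field.attr("dim");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  // corner offsets (ox, oy, oz) of the unit cube
  static const int CO[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing the 0-6 diagonal
  static const int TET[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  double area = 0.0;
  const double *f = field.begin();
  for (int iz = 0; iz + 1 < nz; ++iz)
    for (int ix = 0; ix + 1 < nx; ++ix)
      for (int iy = 0; iy + 1 < ny; ++iy) {
        double cv[8]; double cp[8][3];
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int jx = ix + CO[c][0], jy = iy + CO[c][1], jz = iz + CO[c][2];
          cv[c] = f[jy + (R_xlen_t)ny * (jx + (R_xlen_t)nx * jz)];
          cp[c][0] = jx * dx; cp[c][1] = jy * dy; cp[c][2] = jz * dz;
          if (cv[c] > iso) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          int above[4], nab = 0, below[4], nbe = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[vi[k]] > iso) above[nab++] = vi[k];
            else below[nbe++] = vi[k];
          }
          if (nab == 0 || nab == 4) continue;
          double e[4][3]; int ne = 0;
          if (nab == 1 || nab == 3) {
            int lone = (nab == 1) ? above[0] : below[0];
            int *rest = (nab == 1) ? below : above;
            for (int k = 0; k < 3; ++k) {
              double t0 = (iso - cv[lone]) / (cv[rest[k]] - cv[lone]);
              for (int d = 0; d < 3; ++d)
                e[ne][d] = cp[lone][d] + t0 * (cp[rest[k]][d] - cp[lone][d]);
              ++ne;
            }
            area += tri_area(e[0], e[1], e[2]);
          } else { // 2 above, 2 below: quad through 4 edges
            int pairs[4][2] = {
              {above[0], below[0]}, {above[0], below[1]},
              {above[1], below[1]}, {above[1], below[0]}};
            for (int k = 0; k < 4; ++k) {
              int a = pairs[k][0], b = pairs[k][1];
              double t0 = (iso - cv[a]) / (cv[b] - cv[a]);
              for (int d = 0; d < 3; ++d)
                e[ne][d] = cp[a][d] + t0 * (cp[b][d] - cp[a][d]);
              ++ne;
            }
            area += tri_area(e[0], e[1], e[2]);
            area += tri_area(e[0], e[2], e[3]);
          }
        }
      }
  return area;
}

// Marching-tetrahedra isosurface with vertex welding and optional Taubin
// lambda/mu mesh smoothing; returns the total triangle area. Taubin
// smoothing removes voxel-lattice ripple from the mesh without the
// volume shrinkage of plain Laplacian smoothing, so flat faces stay flat
// while rippled curved surfaces relax to their mean position.
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, double iso,
                           double dy, double dx, double dz,
                           int taubin_iters, double lambda, double mu) {
  IntegerVector dims = field.attr("dim");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  static const int CO[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int TET[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,4,5,6},{0,5,1,6},{0,7,4,6}};

  std::vector<double> vx_, vy_, vz_;        // welded vertices
  std::vector<int> tri;                     // triangle vertex ids
  std::unordered_map<long long, int> weld;
  const double qs = 1e6;                    // weld quantum: 1e-6 units
  const double *f = field.begin();

  auto add_vertex = [&](double x, double y, double z) -> int {
    long long kx = (long long)std::llround(x * qs);
    long long ky = (long long)std::llround(y * qs);
    long long kz = (long long)std::llround(z * qs);
    long long key = ((kx * 1000003LL) ^ (ky * 998244353LL)) * 1000033LL ^ kz;
    auto it = weld.find(key);
    if (it != weld.end()) return it->second;
    int id = (int)vx_.size();
    weld.emplace(key, id);
    vx_.push_back(x); vy_.push_back(y); vz_.push_back(z);
    return id;
  };

  for (int iz = 0; iz + 1 < nz; ++iz)
    for (int ix = 0; ix + 1 < nx; ++ix)
      for (int iy = 0; iy + 1 < ny; ++iy) {
        double cv[8]; double cp[8][3];
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int jx = ix + CO[c][0], jy = iy + CO[c][1], jz = iz + CO[c][2];
          cv[c] = f[jy + (R_xlen_t)ny * (jx + (R_xlen_t)nx * jz)];
          cp[c][0] = jx * dx; cp[c][1] = jy * dy; cp[c][2] = jz * dz;
          if (cv[c] > iso) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          int above[4], nab = 0, below[4], nbe = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[vi[k]] > iso) above[nab++] = vi[k];
            else below[nbe++] = vi[k];
          }
          if (nab == 0 || nab == 4) continue;
          auto interp = [&](int a, int b, double out[3]) {
            // evaluate with consistent operand order for exact welding
            int lo = a < b ? a : b, hi = a < b ? b : a;
            double t0 = (iso - cv[lo]) / (cv[hi] - cv[lo]);
            for (int d2 = 0; d2 < 3; ++d2)
              out[d2] = cp[lo][d2] + t0 * (cp[hi][d2] - cp[lo][d2]);
          };
          double e[4][3]; int ids[4]; int ne = 0;
          if (nab == 1 || nab == 3) {
            int lone = (nab == 1) ? above[0] : below[0];
            int *rest = (nab == 1) ? below : above;
            for (int k = 0; k < 3; ++k) {
              interp(lone, rest[k], e[ne]);
              ids[ne] = add_vertex(e[ne][0], e[ne][1], e[ne][2]);
              ++ne;
            }
            tri.push_back(ids[0]); tri.push_back(ids[1]); tri.push_back(ids[2]);
          } else {
            int pairs[4][2] = {
              {above[0], below[0]}, {above[0], below[1]},
              {above[1], below[1]}, {above[1], below[0]}};
            for (int k = 0; k < 4; ++k) {
              interp(pairs[k][0], pairs[k][1], e[ne]);
              ids[ne] = add_vertex(e[ne][0], e[ne][1], e[ne][2]);
              ++ne;
            }
            tri.push_back(ids[0]); tri.push_back(ids[1]); tri.push_back(ids[2]);
            tri.push_back(ids[0]); tri.push_back(ids[2]); tri.push_back(ids[3]);
          }
        }
      }

  const int nv = (int)vx_.size();
  const int nt = (int)tri.size() / 3;
  if (nv == 0) return 0.0;

  if (taubin_iters > 0) {
    // unique undirected neighbour lists from triangle edges
    std::vector<std::vector<int>> nbr(nv);
    for (int t = 0; t < nt; ++t)
      for (int k = 0; k < 3; ++k) {
        int a = tri[3 * t + k], b = tri[3 * t + (k + 1) % 3];
        nbr[a].push_back(b); nbr[b].push_back(a);
      }
    for (int i = 0; i < nv; ++i) {
      std::sort(nbr[i].begin(), nbr[i].end());
      nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
    }
    std::vector<double> mx(nv), my(nv), mz(nv);
    for (int it = 0; it < 2 * taubin_iters; ++it) {
      double w = (it % 2 == 0) ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        if (nbr[i].empty()) { mx[i] = vx_[i]; my[i] = vy_[i]; mz[i] = vz_[i]; continue; }
        double sx = 0, sy = 0, sz = 0;
        for (int j : nbr[i]) { sx += vx_[j]; sy += vy_[j]; sz += vz_[j]; }
        double n = (double)nbr[i].size();
        mx[i] = vx_[i] + w * (sx / n - vx_[i]);
        my[i] = vy_[i] + w * (sy / n - vy_[i]);
        mz[i] = vz_[i] + w * (sz / n - vz_[i]);
      }
      vx_.swap(mx); vy_.swap(my); vz_.swap(mz);
    }
  }

  double area = 0.0;
  for (int t = 0; t < nt; ++t) {
    int a = tri[3 * t], b = tri[3 * t + 1], c = tri[3 * t + 2];
    double pa[3] = {vx_[a], vy_[a], vz_[a]};
    double pb[3] = {vx_[b], vy_[b], vz_[b]};
    double pc[3] = {vx_[c], vy_[c], vz_[c]};
    area += tri_area(pa, pb, pc);
  }
  return area;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest TRUE voxel of a 3D mask (dim ny, nx, nz; spacing dy, dx, dz).
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector mask, double dy, double dx,
                         double dz) {
  IntegerVector dims = mask.attr("dim");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  out.attr("dim") = mask.attr("dim");
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // along y (stride 1)
  f.resize(ny); d.resize(ny);
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = (R_xlen_t)ny * (ix + (R_xlen_t)nx * iz);
      for (int iy = 0; iy < ny; ++iy) f[iy] = out[base + iy];
      edt1d(f, d, ny, dy);
      for (int iy = 0; iy < ny; ++iy) out[base + iy] = d[iy];
    }
  // along x (stride ny)
  f.resize(nx); d.resize(nx);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = iy + (R_xlen_t)ny * nx * (R_xlen_t)iz;
      for (int ix = 0; ix < nx; ++ix) f[ix] = out[base + (R_xlen_t)ny * ix];
      edt1d(f, d, nx, dx);
      for (int ix = 0; ix < nx; ++ix) out[base + (R_xlen_t)ny * ix] = d[ix];
    }
  // along z (stride ny*nx)
  f.resize(nz); d.resize(nz);
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = iy + (R_xlen_t)ny * ix;
      for (int iz = 0; iz < nz; ++iz) f[iz] = out[base + plane * iz];
      edt1d(f, d, nz, dz);
      for (int iz = 0; iz < nz; ++iz) out[base + plane * iz] = d[iz];
    }
  return out;
}

// Zhang-Suen thinning of a 2D logical matrix down to a 1-pixel skeleton.
// Border pixels are assumed background (callers pad by one pixel).
// [[Rcpp::export]]
LogicalMatrix cpp_thin2d(LogicalMatrix img) {
  int ny = img.nrow(), nx = img.ncol();
  LogicalMatrix cur = clone(img);
  std::vector<std::pair<int,int>> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int x = 1; x + 1 < nx; ++x)
        for (int y = 1; y + 1 < ny; ++y) {
          if (!cur(y, x)) continue;
          // neighbours clockwise from north: P2..P9
          int P[8] = {
            cur(y-1, x), cur(y-1, x+1), cur(y, x+1), cur(y+1, x+1),
            cur(y+1, x), cur(y+1, x-1), cur(y, x-1), cur(y-1, x-1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += P[k];
            if (P[k] == 0 && P[(k+1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (step == 0) {
            if (P[0]*P[2]*P[4] != 0) continue;
            if (P[2]*P[4]*P[6] != 0) continue;
          } else {
            if (P[0]*P[2]*P[6] != 0) continue;
            if (P[0]*P[4]*P[6] != 0) continue;
          }
          kill.push_back({y, x});
        }
      for (size_t k = 0; k < kill.size(); ++k)
        cur(kill[k].first, kill[k].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return cur;
}
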