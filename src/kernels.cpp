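#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); linear index (0-based):
//   i = z + nz * (y + ny * x)

static inline long vidx(int z, int y, int x, int nz, int ny) {
  return (long)z + (long)nz * ((long)y + (long)ny * (long)x);
}

// ---- 3D topological thinning -----------------------------------------------
//
// Iterative removal of simple points (Malandain-Bertrand characterization):
// a foreground voxel p is simple iff
//   T26(p) = number of 26-connected foreground components in N26*(p) == 1
//   T6(p)  = number of 6-connected background components of N18(p)
//            containing a face neighbor == 1
// Deletion proceeds in 6 directional subiterations (U,D,N,S,E,W borders)
// with sequential re-checking, which preserves topology and keeps the
// result a 1-voxel-wide 26-connected centerline. Endpoints (<= 1
// foreground 26-neighbor) are never removed so branch tips survive.

// The endpoint guard is generalized: a voxel is protected when it has at
// most one foreground neighbor (a curve end) or exactly two that are
// mutually 26-adjacent (the blunt front of a 2-voxel-wide strand). The
// second clause stops the sequential re-check from cascading end-to-end
// through an even-symmetric rod — whose shrinking front voxel always
// stays topologically simple — which would otherwise collapse the whole
// rod within one pass. Interior voxels of 1-voxel curves have two
// *opposite* (non-adjacent) neighbors and are protected by non-simplicity
// as usual.

// decode cube cell index c (0..26) to offsets in {-1,0,1}
static inline void cube_dec(int c, int &dz, int &dy, int &dx) {
  dz = c % 3 - 1; dy = (c / 3) % 3 - 1; dx = c / 9 - 1;
}

static bool is_simple(const unsigned char *nb) {
  // nb: 27 values, nb[13] is the center (ignored)
  // T26: foreground components among the 26 neighbors, 26-adjacency
  int label[27]; for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp26 = 0;
  int stack[27];
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !nb[c] || label[c] >= 0) continue;
    ++ncomp26;
    if (ncomp26 > 1) return false;
    int top = 0; stack[top++] = c; label[c] = ncomp26;
    while (top) {
      int u = stack[--top];
      int uz, uy, ux; cube_dec(u, uz, uy, ux);
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || !nb[v] || label[v] >= 0) continue;
        int vz, vy, vx; cube_dec(v, vz, vy, vx);
        if (std::abs(uz - vz) <= 1 && std::abs(uy - vy) <= 1 &&
            std::abs(ux - vx) <= 1) {
          label[v] = ncomp26; stack[top++] = v;
        }
      }
    }
  }
  if (ncomp26 != 1) return false;

  // T6: background components in the 18-neighborhood, 6-adjacency,
  // seeded from face neighbors
  for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp6 = 0;
  for (int c = 0; c < 27; ++c) {
    int cz, cy, cx; cube_dec(c, cz, cy, cx);
    int manh = std::abs(cz) + std::abs(cy) + std::abs(cx);
    if (manh != 1 || nb[c] || label[c] >= 0) continue; // seed: background face nbr
    ++ncomp6;
    if (ncomp6 > 1) return false;
    int top = 0; stack[top++] = c; label[c] = ncomp6;
    while (top) {
      int u = stack[--top];
      int uz, uy, ux; cube_dec(u, uz, uy, ux);
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || nb[v] || label[v] >= 0) continue;
        int vz, vy, vx; cube_dec(v, vz, vy, vx);
        if (std::abs(vz) + std::abs(vy) + std::abs(vx) > 2) continue; // N18 only
        if (std::abs(uz - vz) + std::abs(uy - vy) + std::abs(ux - vx) == 1) {
          label[v] = ncomp6; stack[top++] = v;
        }
      }
    }
  }
  return ncomp6 == 1;
}

static inline void fill_nb(const std::vector<unsigned char> &vol, int z, int y,
                           int x, int nz, int ny, int nx, unsigned char *nb) {
  int c = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        // cube index consistent with cube_dec: c = (dz+1)+3*(dy+1)+9*(dx+1)
        int ci = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
        nb[ci] = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 &&
                  xx < nx)
                     ? vol[vidx(zz, yy, xx, nz, ny)]
                     : 0;
        (void)c;
      }
}

static inline int count_fg26(const unsigned char *nb) {
  int n = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && nb[c]) ++n;
  return n;
}

// curve-end protection: <= 1 fg neighbor, or exactly 2 that are mutually
// 26-adjacent (blunt front of a 2-wide strand)
static inline bool is_protected_end(const unsigned char *nb) {
  int ids[3], n = 0;
  for (int c = 0; c < 27 && n <= 2; ++c)
    if (c != 13 && nb[c]) { if (n < 3) ids[n] = c; ++n; }
  if (n <= 1) return true;
  if (n == 2) {
    int az, ay, ax, bz, by, bx;
    cube_dec(ids[0], az, ay, ax);
    cube_dec(ids[1], bz, by, bx);
    return std::abs(az - bz) <= 1 && std::abs(ay - by) <= 1 &&
           std::abs(ax - bx) <= 1;
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  std::vector<unsigned char> vol(n);
  for (long i = 0; i < n; ++i) vol[i] = mask[i] != 0;

  // 6 border directions (dz,dy,dx)
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  unsigned char nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            long i = vidx(z, y, x, nz, ny);
            if (!vol[i]) continue;
            int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            bool border = !(zz >= 0 && zz < nz && yy >= 0 && yy < ny &&
                            xx >= 0 && xx < nx) ||
                          !vol[vidx(zz, yy, xx, nz, ny)];
            if (!border) continue;
            fill_nb(vol, z, y, x, nz, ny, nx, nb);
            if (is_protected_end(nb)) continue;
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential re-check then delete (each deletion topology-safe)
      for (size_t k = 0; k < cand.size(); ++k) {
        long i = cand[k];
        int x = (int)(i / ((long)nz * ny));
        int rem = (int)(i - (long)x * nz * ny);
        int y = rem / nz, z = rem % nz;
        fill_nb(vol, z, y, x, nz, ny, nx, nb);
        if (is_protected_end(nb)) continue;
        if (is_simple(nb)) {
          vol[i] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = vol[i];
  out.attr("dim") = dims;
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) --------
// squared-distance lower envelope of parabolas, run separably per axis with
// physical sample spacing, so anisotropic voxels give distances in microns.

static void dt1d(std::vector<double> &f, std::vector<double> &d, double w,
                 std::vector<int> &v, std::vector<double> &zb) {
  int n = (int)f.size();
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  const double INF = 1e30;
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = out[vidx(z, y, x, nz, ny)];
      d.assign(nz, 0.0);
      dt1d(f, d, spacing[0], v, zb);
      for (int z = 0; z < nz; ++z) out[vidx(z, y, x, nz, ny)] = d[z];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = out[vidx(z, y, x, nz, ny)];
      d.assign(ny, 0.0);
      dt1d(f, d, spacing[1], v, zb);
      for (int y = 0; y < ny; ++y) out[vidx(z, y, x, nz, ny)] = d[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = out[vidx(z, y, x, nz, ny)];
      d.assign(nx, 0.0);
      dt1d(f, d, spacing[2], v, zb);
      for (int x = 0; x < nx; ++x) out[vidx(z, y, x, nz, ny)] = d[x];
    }
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// ---- Perona-Malik nonlinear diffusion --------------------------------------
// Explicit scheme, conductance g2(s) = 1 / (1 + (s/K)^2), Neumann borders.
// Snapshots of the evolving image are returned at the requested cumulative
// times (the nonlinear scale-space levels). tau must be <= 0.25 for
// stability of the 4-neighbor explicit discretization.

// [[Rcpp::export]]
List cpp_pm_diffuse(NumericMatrix img, NumericVector times, double tau,
                    double K) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> I(img.begin(), img.end());
  std::vector<double> g(nr * nc), J(nr * nc);
  double K2 = K * K;
  List out(times.size());
  double t = 0.0;
  int snap = 0;
  auto at = [&](int r, int c) { return I[r + (long)nr * c]; };
  // emit any snapshots requested at t = 0
  while (snap < times.size() && times[snap] <= 1e-12) {
    NumericMatrix m(nr, nc);
    std::copy(I.begin(), I.end(), m.begin());
    out[snap++] = m;
  }
  while (snap < times.size()) {
    double step = std::min(tau, times[snap] - t);
    // conductance from central-difference gradient magnitude
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int rm = r > 0 ? r - 1 : 0, rp = r < nr - 1 ? r + 1 : nr - 1;
        int cm = c > 0 ? c - 1 : 0, cp = c < nc - 1 ? c + 1 : nc - 1;
        double gx = 0.5 * (at(r, cp) - at(r, cm));
        double gy = 0.5 * (at(rp, c) - at(rm, c));
        g[r + (long)nr * c] = 1.0 / (1.0 + (gx * gx + gy * gy) / K2);
      }
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int rm = r > 0 ? r - 1 : 0, rp = r < nr - 1 ? r + 1 : nr - 1;
        int cm = c > 0 ? c - 1 : 0, cp = c < nc - 1 ? c + 1 : nc - 1;
        long i = r + (long)nr * c;
        double gi = g[i];
        double flux =
            0.5 * (gi + g[rm + (long)nr * c]) * (at(rm, c) - at(r, c)) +
            0.5 * (gi + g[rp + (long)nr * c]) * (at(rp, c) - at(r, c)) +
            0.5 * (gi + g[r + (long)nr * cm]) * (at(r, cm) - at(r, c)) +
            0.5 * (gi + g[r + (long)nr * cp]) * (at(r, cp) - at(r, c));
        J[i] = I[i] + step * flux;
      }
    I.swap(J);
    t += step;
    while (snap < times.size() && t >= times[snap] - 1e-9) {
      NumericMatrix m(nr, nc);
      std::copy(I.begin(), I.end(), m.begin());
      out[snap++] = m;
    }
  }
  return out;
}
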