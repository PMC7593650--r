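#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Index helpers for column-major 3D arrays (R layout).
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Half-sample symmetric reflection of index i into [0, n).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector arr, IntegerVector dim, NumericVector kernel, int axis) {
  // 1D correlation along `axis` (1,2,3) with half-sample reflective boundary.
  // Kernel must be symmetric for the reflection to conserve the image sum.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int kn = kernel.size();
  int kh = (kn - 1) / 2;
  NumericVector out(arr.size());
  const double* a = arr.begin();
  double* o = out.begin();
  const double* kv = kernel.begin();

  if (axis == 1) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = idx3(0, j, k, nx, ny);
        for (int i = 0; i < nx; ++i) {
          double s = 0.0;
          for (int t = 0; t < kn; ++t)
            s += kv[t] * a[base + reflect_idx(i + t - kh, nx)];
          o[base + i] = s;
        }
      }
  } else if (axis == 2) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) {
          double s = 0.0;
          for (int t = 0; t < kn; ++t)
            s += kv[t] * a[idx3(i, reflect_idx(j + t - kh, ny), k, nx, ny)];
          o[idx3(i, j, k, nx, ny)] = s;
        }
      }
  } else {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) {
          double s = 0.0;
          for (int t = 0; t < kn; ++t)
            s += kv[t] * a[idx3(i, j, reflect_idx(k + t - kh, nz), nx, ny)];
          o[idx3(i, j, k, nx, ny)] = s;
        }
      }
  }
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample spacing s.
static void dt1d(const double* f, double* d, int n, double s, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sint;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      // intersection abscissa in physical units (sample q sits at x = q*s)
      sint = ((fq + (double)q * q * s2) - (fv + (double)v[k] * v[k] * s2)) /
             (2.0 * s * (q - v[k]));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = (double)q * s;
    while (z[k + 1] < x) ++k;
    double dx = ((double)q - (double)v[k]) * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  // Squared Euclidean distance (physical units) to the nearest TRUE voxel centre.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  double* dd = d.begin();

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = idx3(0, j, k, nx, ny);
      dt1d(dd + base, g.data(), nx, spacing[0], v.data(), z.data());
      std::copy(g.begin(), g.begin() + nx, dd + base);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = dd[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), g.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) dd[idx3(i, j, k, nx, ny)] = g[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = dd[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), g.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; ++k) dd[idx3(i, j, k, nx, ny)] = g[k];
    }
  return d;
}

// [[Rcpp::export(name = ".resample_trilinear")]]
NumericVector resample_trilinear(NumericVector src, IntegerVector sdim,
                                 NumericVector sspacing, NumericVector sorigin,
                                 IntegerVector tdim, NumericVector tspacing,
                                 NumericVector torigin, NumericMatrix R,
                                 NumericVector tvec, double fill) {
  // For each target voxel centre y, sample source at x = R y + t (pull-back).
  int nx = tdim[0], ny = tdim[1], nz = tdim[2];
  int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* s = src.begin();
  double* o = out.begin();
  for (int k = 0; k < nz; ++k) {
    double zc = torigin[2] + tspacing[2] * k;
    for (int j = 0; j < ny; ++j) {
      double yc = torigin[1] + tspacing[1] * j;
      for (int i = 0; i < nx; ++i) {
        double xc = torigin[0] + tspacing[0] * i;
        double px = R(0,0)*xc + R(0,1)*yc + R(0,2)*zc + tvec[0];
        double py = R(1,0)*xc + R(1,1)*yc + R(1,2)*zc + tvec[1];
        double pz = R(2,0)*xc + R(2,1)*yc + R(2,2)*zc + tvec[2];
        double u = (px - sorigin[0]) / sspacing[0];
        double v = (py - sorigin[1]) / sspacing[1];
        double w = (pz - sorigin[2]) / sspacing[2];
        int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
        // samples landing exactly on the last plane are valid: clamp the
        // base cell so interpolation weights become (0, 1)
        if (i0 == sx - 1 && u <= sx - 1 + 1e-9) i0 = sx - 2;
        if (j0 == sy - 1 && v <= sy - 1 + 1e-9) j0 = sy - 2;
        if (k0 == sz - 1 && w <= sz - 1 + 1e-9) k0 = sz - 2;
        double val;
        if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= sx - 1 || j0 >= sy - 1 || k0 >= sz - 1) {
          val = fill;
        } else {
          double fu = u - i0, fv = v - j0, fw = w - k0;
          double c000 = s[idx3(i0,     j0,     k0,     sx, sy)];
          double c100 = s[idx3(i0 + 1, j0,     k0,     sx, sy)];
          double c010 = s[idx3(i0,     j0 + 1, k0,     sx, sy)];
          double c110 = s[idx3(i0 + 1, j0 + 1, k0,     sx, sy)];
          double c001 = s[idx3(i0,     j0,     k0 + 1, sx, sy)];
          double c101 = s[idx3(i0 + 1, j0,     k0 + 1, sx, sy)];
          double c011 = s[idx3(i0,     j0 + 1, k0 + 1, sx, sy)];
          double c111 = s[idx3(i0 + 1, j0 + 1, k0 + 1, sx, sy)];
          double c00 = c000 * (1 - fu) + c100 * fu;
          double c10 = c010 * (1 - fu) + c110 * fu;
          double c01 = c001 * (1 - fu) + c101 * fu;
          double c11 = c011 * (1 - fu) + c111 * fu;
          double c0 = c00 * (1 - fv) + c10 * fv;
          double c1 = c01 * (1 - fv) + c11 * fv;
          val = c0 * (1 - fw) + c1 * fw;
        }
        o[idx3(i, j, k, nx, ny)] = val;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  // 6-connected component labelling, labels 1..K in scan order of seeds.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s0 = 0; s0 < n; ++s0) {
    if (!mask[s0] || lab[s0]) continue;
    ++cur;
    stack.push_back(s0);
    lab[s0] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % nx;
      int j = (p / nx) % ny;
      int k = p / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t q = idx3(ii, jj, kk, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out, double* bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; bary[0]=1;bary[1]=0;bary[2]=0; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; bary[0]=0;bary[1]=1;bary[2]=0; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
    bary[0]=1-v; bary[1]=v; bary[2]=0; return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; bary[0]=0;bary[1]=0;bary[2]=1; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
    bary[0]=1-w; bary[1]=0; bary[2]=w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i]-b[i]);
    bary[0]=0; bary[1]=1-w; bary[2]=w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
  bary[0]=1-v-w; bary[1]=v; bary[2]=w;
}

// [[Rcpp::export(name = ".project_points_tris")]]
List project_points_tris(NumericMatrix pts, NumericMatrix tv, double max_dist) {
  // pts: m x 3; tv: nt x 9 (v0x v0y v0z v1x ... v2z).
  // Returns nearest triangle index (1-based, 0 if farther than max_dist),
  // closest point, barycentric coords and distance for each point.
  int m = pts.nrow(), nt = tv.nrow();
  IntegerVector tri(m, 0);
  NumericMatrix cp(m, 3), bc(m, 3);
  NumericVector dist(m, NA_REAL);
  if (nt == 0) return List::create(_["tri"]=tri, _["point"]=cp, _["bary"]=bc, _["dist"]=dist);

  // Uniform grid over triangle AABBs.
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = 1e300; hi[d] = -1e300; }
  double esum = 0;
  for (int t = 0; t < nt; ++t) {
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d) {
        double x = tv(t, 3*v + d);
        if (x < lo[d]) lo[d] = x;
        if (x > hi[d]) hi[d] = x;
      }
    double e = 0;
    for (int d = 0; d < 3; ++d) { double dd = tv(t,d) - tv(t,3+d); e += dd*dd; }
    esum += std::sqrt(e);
  }
  double cell = std::max(esum / nt, 1e-9) * 2.0;
  int ng[3];
  for (int d = 0; d < 3; ++d) {
    ng[d] = std::max(1, std::min(128, (int)std::ceil((hi[d] - lo[d]) / cell) + 1));
  }
  // recompute per-axis cell so grid covers the box
  double cw[3];
  for (int d = 0; d < 3; ++d) cw[d] = std::max((hi[d] - lo[d]) / ng[d], 1e-9);

  R_xlen_t ncell = (R_xlen_t)ng[0]*ng[1]*ng[2];
  std::vector<std::vector<int> > bins(ncell);
  for (int t = 0; t < nt; ++t) {
    double tlo[3], thi[3];
    for (int d = 0; d < 3; ++d) { tlo[d] = 1e300; thi[d] = -1e300; }
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d) {
        double x = tv(t, 3*v + d);
        if (x < tlo[d]) tlo[d] = x;
        if (x > thi[d]) thi[d] = x;
      }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = std::max(0, std::min(ng[d]-1, (int)((tlo[d] - lo[d]) / cw[d])));
      c1[d] = std::max(0, std::min(ng[d]-1, (int)((thi[d] - lo[d]) / cw[d])));
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[idx3(i, j, k, ng[0], ng[1])].push_back(t);
  }
  double cmin = std::min(cw[0], std::min(cw[1], cw[2]));
  int maxring = (int)std::ceil(max_dist / cmin) + 1;

  for (int p = 0; p < m; ++p) {
    double pt[3] = { pts(p,0), pts(p,1), pts(p,2) };
    int pc[3];
    for (int d = 0; d < 3; ++d)
      pc[d] = std::max(0, std::min(ng[d]-1, (int)((pt[d] - lo[d]) / cw[d])));
    double best = max_dist * max_dist;
    int bestt = -1;
    double bestcp[3] = {0,0,0}, bestbc[3] = {0,0,0};
    for (int ring = 0; ring <= maxring; ++ring) {
      // stop if a hit is guaranteed closer than anything in farther rings
      if (bestt >= 0) {
        double clearance = (ring - 1) * cmin;
        if (clearance > 0 && best <= clearance * clearance) break;
      }
      bool any = false;
      for (int k = std::max(0, pc[2]-ring); k <= std::min(ng[2]-1, pc[2]+ring); ++k)
        for (int j = std::max(0, pc[1]-ring); j <= std::min(ng[1]-1, pc[1]+ring); ++j)
          for (int i = std::max(0, pc[0]-ring); i <= std::min(ng[0]-1, pc[0]+ring); ++i) {
            int cd = std::max(std::abs(i-pc[0]), std::max(std::abs(j-pc[1]), std::abs(k-pc[2])));
            if (cd != ring) continue; // only the new shell
            any = true;
            const std::vector<int>& b = bins[idx3(i, j, k, ng[0], ng[1])];
            for (size_t q = 0; q < b.size(); ++q) {
              int t = b[q];
              double a0[3] = { tv(t,0), tv(t,1), tv(t,2) };
              double a1[3] = { tv(t,3), tv(t,4), tv(t,5) };
              double a2[3] = { tv(t,6), tv(t,7), tv(t,8) };
              double cpt[3], bct[3];
              closest_on_tri(pt, a0, a1, a2, cpt, bct);
              double d2 = 0;
              for (int d = 0; d < 3; ++d) { double dd = pt[d]-cpt[d]; d2 += dd*dd; }
              if (d2 < best) {
                best = d2; bestt = t;
                for (int d = 0; d < 3; ++d) { bestcp[d]=cpt[d]; bestbc[d]=bct[d]; }
              }
            }
          }
      if (!any && ring > 0 && bestt >= 0) break;
      if (!any && ring > 0 &&
          (pc[0]-ring < 0 && pc[0]+ring >= ng[0] &&
           pc[1]-ring < 0 && pc[1]+ring >= ng[1] &&
           pc[2]-ring < 0 && pc[2]+ring >= ng[2])) break;
    }
    if (bestt >= 0) {
      tri[p] = bestt + 1;
      dist[p] = std::sqrt(best);
      for (int d = 0; d < 3; ++d) { cp(p,d) = bestcp[d]; bc(p,d) = bestbc[d]; }
    }
  }
  return List::create(_["tri"]=tri, _["point"]=cp, _["bary"]=bc, _["dist"]=dist);
}
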