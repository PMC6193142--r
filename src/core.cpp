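// Low-level resampling, projection and alignment kernels.
//
// Conventions (shared with the R layer):
//  * volumes are arrays vol[x, y, z], filament axis along z (third index);
//  * images are matrices img[u, t]: u transverse, t axial (same axis as z);
//  * all rotations use the pixel centre c = (n + 1) / 2 in 1-based
//    coordinates, so 90/180 degree rotations of square grids are exact;
//  * angles in degrees, counter-clockwise in the (x, y) plane for azimuth,
//    in the (u, t) plane for in-plane rotation;
//  * out-of-support samples are zero.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// bilinear lookup into an nx * ny matrix stored column-major (0-based coords)
static inline double bilin(const double* m, int nx, int ny, double x, double y) {
  // tolerate rounding at the support boundary (exact 90/180 deg rotations)
  const double eps = 1e-9;
  if (x < 0.0 && x > -eps) x = 0.0;
  if (y < 0.0 && y > -eps) y = 0.0;
  if (x > nx - 1.0 && x < nx - 1.0 + eps) x = nx - 1.0;
  if (y > ny - 1.0 && y < ny - 1.0 + eps) y = ny - 1.0;
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  if (ix == nx - 1) ix--;
  if (iy == ny - 1) iy--;
  double fx = x - ix, fy = y - iy;
  const double* p = m + (size_t)iy * nx + ix;
  double v00 = p[0], v10 = p[1], v01 = p[nx], v11 = p[nx + 1];
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_image(NumericMatrix img, double psi_deg) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double cs = std::cos(-psi_deg * DEG), sn = std::sin(-psi_deg * DEG);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double dy = j - cy;
    for (int i = 0; i < nx; ++i) {
      double dx = i - cx;
      out(i, j) = bilin(&img[0], nx, ny, cx + cs * dx - sn * dy,
                        cy + sn * dx + cs * dy);
    }
  }
  return out;
}

// forward transform: out(p) = img evaluated at c + delta + R(psi) (p - c)
// With (psi, dx, dy) from an alignment record this undoes
// shift(delta) o rotate(psi) in a single resampling pass.
// [[Rcpp::export]]
NumericMatrix cpp_unalign_image(NumericMatrix img, double psi_deg,
                                double dx, double dy) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double cs = std::cos(psi_deg * DEG), sn = std::sin(psi_deg * DEG);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double py = j - cy;
    for (int i = 0; i < nx; ++i) {
      double px = i - cx;
      out(i, j) = bilin(&img[0], nx, ny, cx + dx + cs * px - sn * py,
                        cy + dy + sn * px + cs * py);
    }
  }
  return out;
}

// apply the generative transform: shift(delta) o rotate(psi):
// out(p) = img(c + R(-psi) (p - delta - c))
// [[Rcpp::export]]
NumericMatrix cpp_apply_inplane(NumericMatrix img, double psi_deg,
                                double dx, double dy) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double cs = std::cos(-psi_deg * DEG), sn = std::sin(-psi_deg * DEG);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double py = j - cy - dy;
    for (int i = 0; i < nx; ++i) {
      double px = i - cx - dx;
      out(i, j) = bilin(&img[0], nx, ny, cx + cs * px - sn * py,
                        cy + sn * px + cs * py);
    }
  }
  return out;
}

// project volume rotated about z by phi, integrating along y
// [[Rcpp::export]]
NumericMatrix cpp_project_z(NumericVector vol, IntegerVector dim,
                            double phi_deg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double cs = std::cos(phi_deg * DEG), sn = std::sin(phi_deg * DEG);
  NumericMatrix out(nx, nz);
  const double* v = &vol[0];
  std::vector<double> acc((size_t)nx, 0.0);
  for (int iz = 0; iz < nz; ++iz) {
    const double* slab = v + (size_t)iz * nx * ny;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < ny; ++t) {
      double dt = t - cy;
      for (int u = 0; u < nx; ++u) {
        double du = u - cx;
        // rotate sample point by -phi: vol coords
        double x = cx + cs * du + sn * dt;
        double y = cy - sn * du + cs * dt;
        acc[u] += bilin(slab, nx, ny, x, y);
      }
    }
    for (int u = 0; u < nx; ++u) out(u, iz) = acc[u];
  }
  return out;
}

// accumulate ramp-filtered projections back along their azimuths
// imgs: nx x nz x k, phis length k; returns nx*ny*nz volume (ny = nx)
// [[Rcpp::export]]
NumericVector cpp_backproject_z(NumericVector imgs, IntegerVector idim,
                                NumericVector phis, NumericVector weights) {
  int nx = idim[0], nz = idim[1], k = idim[2];
  int ny = nx;
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  NumericVector vol((size_t)nx * ny * nz);
  double* v = &vol[0];
  for (int p = 0; p < k; ++p) {
    const double* im = &imgs[0] + (size_t)p * nx * nz;
    double cs = std::cos(phis[p] * DEG), sn = std::sin(phis[p] * DEG);
    double w = weights[p];
    // u(x, y) = cx + cs (x - cx) - sn (y - cy)
    for (int iz = 0; iz < nz; ++iz) {
      const double* col = im + (size_t)iz * nx;
      double* slab = v + (size_t)iz * nx * ny;
      for (int iy = 0; iy < ny; ++iy) {
        double base = cx - sn * (iy - cy);
        double* row = slab + (size_t)iy * nx;
        for (int ix = 0; ix < nx; ++ix) {
          double u = base + cs * (ix - cx);
          if (u < 0.0 || u > nx - 1.0) continue;
          int iu = (int)std::floor(u);
          if (iu == nx - 1) iu--;
          double f = u - iu;
          row[ix] += w * (col[iu] * (1 - f) + col[iu + 1] * f);
        }
      }
    }
  }
  return vol;
}

// tilt projection about the y axis (beam along z after tilting)
// [[Rcpp::export]]
NumericMatrix cpp_project_tilt(NumericVector vol, IntegerVector dim,
                               double alpha_deg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cs = std::cos(alpha_deg * DEG), sn = std::sin(alpha_deg * DEG);
  NumericMatrix out(nx, ny);
  const double* v = &vol[0];
  for (int iy = 0; iy < ny; ++iy) {
    for (int u = 0; u < nx; ++u) {
      double du = u - cx, s = 0.0;
      for (int t = 0; t < nz; ++t) {
        double dt = t - cz;
        double x = cx + cs * du + sn * dt;
        double z = cz - sn * du + cs * dt;
        if (x < 0.0 || x > nx - 1.0 || z < 0.0 || z > nz - 1.0) continue;
        int ix = (int)std::floor(x), izl = (int)std::floor(z);
        if (ix == nx - 1) ix--;
        if (izl == nz - 1) izl--;
        double fx = x - ix, fz = z - izl;
        const double* p0 = v + (size_t)izl * nx * ny + (size_t)iy * nx + ix;
        const double* p1 = p0 + (size_t)nx * ny;
        s += (p0[0] * (1 - fx) + p0[1] * fx) * (1 - fz) +
             (p1[0] * (1 - fx) + p1[1] * fx) * fz;
      }
      out(u, iy) = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_backproject_tilt(NumericVector imgs, IntegerVector idim,
                                   NumericVector alphas, NumericVector weights,
                                   int nz) {
  int nx = idim[0], ny = idim[1], k = idim[2];
  double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector vol((size_t)nx * ny * nz);
  double* v = &vol[0];
  for (int p = 0; p < k; ++p) {
    const double* im = &imgs[0] + (size_t)p * nx * ny;
    double cs = std::cos(alphas[p] * DEG), sn = std::sin(alphas[p] * DEG);
    double w = weights[p];
    for (int iz = 0; iz < nz; ++iz) {
      double zpart = -sn * (iz - cz);
      double* slab = v + (size_t)iz * nx * ny;
      for (int iy = 0; iy < ny; ++iy) {
        const double* col = im + (size_t)iy * nx;
        double* row = slab + (size_t)iy * nx;
        for (int ix = 0; ix < nx; ++ix) {
          double u = cx + cs * (ix - cx) + zpart;
          if (u < 0.0 || u > nx - 1.0) continue;
          int iu = (int)std::floor(u);
          if (iu == nx - 1) iu--;
          double f = u - iu;
          row[ix] += w * (col[iu] * (1 - f) + col[iu + 1] * f);
        }
      }
    }
  }
  return vol;
}

// rotate a volume about z (per-slice 2D rotation)
// [[Rcpp::export]]
NumericVector cpp_rotate_volume_z(NumericVector vol, IntegerVector dim,
                                  double phi_deg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double cs = std::cos(-phi_deg * DEG), sn = std::sin(-phi_deg * DEG);
  NumericVector out((size_t)nx * ny * nz);
  const double* v = &vol[0];
  double* o = &out[0];
  for (int iz = 0; iz < nz; ++iz) {
    const double* slab = v + (size_t)iz * nx * ny;
    double* oslab = o + (size_t)iz * nx * ny;
    for (int j = 0; j < ny; ++j) {
      double dy = j - cy;
      for (int i = 0; i < nx; ++i) {
        double dx = i - cx;
        oslab[(size_t)j * nx + i] =
            bilin(slab, nx, ny, cx + cs * dx - sn * dy, cy + sn * dx + cs * dy);
      }
    }
  }
  return out;
}

// trilinear interpolation at arbitrary points (1-based coords from R)
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericVector x, NumericVector y, NumericVector z) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = x.size();
  NumericVector out(n);
  const double* v = &vol[0];
  for (int i = 0; i < n; ++i) {
    double xx = x[i] - 1.0, yy = y[i] - 1.0, zz = z[i] - 1.0;
    if (xx < 0 || yy < 0 || zz < 0 || xx > nx - 1.0 || yy > ny - 1.0 ||
        zz > nz - 1.0) {
      out[i] = 0.0;
      continue;
    }
    int ix = (int)std::floor(xx), iy = (int)std::floor(yy),
        iz = (int)std::floor(zz);
    if (ix == nx - 1) ix--;
    if (iy == ny - 1) iy--;
    if (iz == nz - 1) iz--;
    double fx = xx - ix, fy = yy - iy, fz = zz - iz;
    const double* p = v + ((size_t)iz * ny + iy) * nx + ix;
    size_t sxy = (size_t)nx * ny;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
    double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
    double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
    out[i] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive polar alignment engine.
//
// For every particle, searches (reference) x (psi on a regular grid of
// ntheta = 360/psi_step angles) x (integer shifts within shift_max),
// scoring by Pearson correlation over a ring-weighted polar resampling of
// the disk r in [rmin, rmax] centred on the shifted particle centre.  The
// disk is rotation invariant, so per candidate shift the patch statistics
// are computed once and the whole psi grid is scored with per-ring circular
// cross-correlations evaluated through small real DFTs.
// ---------------------------------------------------------------------------

struct PolarPlan {
  int nr, ntheta, nf;
  std::vector<double> ex, ey;     // r * cos/sin(theta), nr*ntheta
  std::vector<double> wroot;      // sqrt(ring weight / ntheta), length nr
  std::vector<double> w;          // ring weights, normalised, length nr
  std::vector<double> fct, fsn;   // forward DFT tables, col-major nf x ntheta
  std::vector<double> inv;        // inverse table, col-major 2nf x ntheta
};

static void plan_polar(PolarPlan& P, int rmin, int rmax, int ntheta,
                       int rstep) {
  P.nr = (rmax - rmin) / rstep + 1;
  P.ntheta = ntheta;
  P.nf = ntheta / 2 + 1;
  P.ex.resize((size_t)P.nr * ntheta);
  P.ey.resize((size_t)P.nr * ntheta);
  P.w.resize(P.nr);
  P.wroot.resize(P.nr);
  double wsum = 0.0;
  for (int r = 0; r < P.nr; ++r) {
    double rad = rmin + (double)r * rstep;
    P.w[r] = rad;
    wsum += rad;
    for (int j = 0; j < ntheta; ++j) {
      double th = 2.0 * M_PI * j / ntheta;
      P.ex[(size_t)r * ntheta + j] = rad * std::cos(th);
      P.ey[(size_t)r * ntheta + j] = rad * std::sin(th);
    }
  }
  for (int r = 0; r < P.nr; ++r) {
    P.w[r] /= (wsum * ntheta);
    P.wroot[r] = std::sqrt(P.w[r]);
  }
  int nf = P.nf;
  P.fct.resize((size_t)nf * ntheta);
  P.fsn.resize((size_t)nf * ntheta);
  P.inv.resize((size_t)2 * nf * ntheta);
  for (int j = 0; j < ntheta; ++j) {
    for (int f = 0; f < nf; ++f) {
      double a = 2.0 * M_PI * f * j / ntheta;
      P.fct[(size_t)j * nf + f] = std::cos(a);
      P.fsn[(size_t)j * nf + f] = -std::sin(a);
      double fw = ((f == 0 || 2 * f == ntheta) ? 1.0 : 2.0) / ntheta;
      P.inv[(size_t)j * 2 * nf + f] = fw * std::cos(a);
      P.inv[(size_t)j * 2 * nf + nf + f] = -fw * std::sin(a);
    }
  }
}

// polar-resample img about centre + (dx, dy) into S (col-major ntheta x nr,
// ring weights folded in), normalised to zero weighted mean / unit weighted
// variance; false when the patch is flat
static bool polar_sample(const double* img, int nx, int ny,
                         const PolarPlan& P, double dx, double dy,
                         std::vector<double>& S) {
  double cx = (nx - 1) / 2.0 + dx, cy = (ny - 1) / 2.0 + dy;
  int nr = P.nr, nt = P.ntheta;
  double mean = 0.0;
  for (int r = 0; r < nr; ++r) {
    double* col = &S[(size_t)r * nt];
    const double* exr = &P.ex[(size_t)r * nt];
    const double* eyr = &P.ey[(size_t)r * nt];
    double rs = 0.0;
    for (int j = 0; j < nt; ++j) {
      col[j] = bilin(img, nx, ny, cx + exr[j], cy + eyr[j]);
      rs += col[j];
    }
    mean += P.w[r] * rs;
  }
  double var = 0.0;
  for (int r = 0; r < nr; ++r) {
    double* col = &S[(size_t)r * nt];
    double vs = 0.0;
    for (int j = 0; j < nt; ++j) {
      col[j] -= mean;
      vs += col[j] * col[j];
    }
    var += P.w[r] * vs;
  }
  if (var <= 1e-300) return false;
  double inv = 1.0 / std::sqrt(var);
  for (int r = 0; r < nr; ++r) {
    double* col = &S[(size_t)r * nt];
    double sw = P.wroot[r] * inv;
    for (int j = 0; j < nt; ++j) col[j] *= sw;
  }
  return true;
}

// forward per-ring real DFT of S: FA/FB are nf x nr (col-major)
static void ring_dft(const PolarPlan& P, const std::vector<double>& S,
                     std::vector<double>& FA, std::vector<double>& FB) {
  const int m = P.nf, n = P.nr, k = P.ntheta;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, P.fct.data(), &m, S.data(), &k,
                  &zero, FA.data(), &m FCONE FCONE);
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, P.fsn.data(), &m, S.data(), &k,
                  &zero, FB.data(), &m FCONE FCONE);
}

// direct correlation of two weight-folded polar patches at angular lag k
static double lag_corr(const PolarPlan& P, const std::vector<double>& S,
                       const double* R, int lag) {
  int nt = P.ntheta, nr = P.nr;
  double acc = 0.0;
  for (int r = 0; r < nr; ++r) {
    const double* sc = &S[(size_t)r * nt];
    const double* rc = R + (size_t)r * nt;
    for (int j = 0; j < nt; ++j) {
      int jm = j - lag;
      if (jm < 0) jm += nt;
      acc += sc[j] * rc[jm];
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_align_polar(NumericVector particles, IntegerVector pdim,
                              NumericVector refs, IntegerVector rdim,
                              int ntheta, int shift_max, int rmin, int rmax,
                              int rstep) {
  int nx = pdim[0], ny = pdim[1], np = pdim[2];
  int nref = rdim[2];
  PolarPlan P;
  plan_polar(P, rmin, rmax, ntheta, rstep);
  int nf = P.nf, nr = P.nr;
  size_t spec_sz = (size_t)nf * nr;

  // reference polar patches and ring spectra (no shift)
  std::vector<double> rsamp((size_t)nref * nr * ntheta);
  std::vector<double> rA((size_t)nref * spec_sz), rB((size_t)nref * spec_sz);
  std::vector<double> S((size_t)nr * ntheta);
  std::vector<double> FA(spec_sz), FB(spec_sz);
  std::vector<bool> refok(nref);
  for (int rf = 0; rf < nref; ++rf) {
    const double* rimg = &refs[0] + (size_t)rf * nx * ny;
    refok[rf] = polar_sample(rimg, nx, ny, P, 0.0, 0.0, S);
    std::copy(S.begin(), S.end(), rsamp.begin() + (size_t)rf * nr * ntheta);
    ring_dft(P, S, FA, FB);
    std::copy(FA.begin(), FA.end(), rA.begin() + rf * spec_sz);
    std::copy(FB.begin(), FB.end(), rB.begin() + rf * spec_sz);
  }

  // shift grid ordered by |delta| (then dy, dx) for deterministic tie-breaks
  std::vector<std::array<int, 2>> shifts;
  for (int dy = -shift_max; dy <= shift_max; ++dy)
    for (int dx = -shift_max; dx <= shift_max; ++dx)
      shifts.push_back({dx, dy});
  std::stable_sort(shifts.begin(), shifts.end(),
                   [](const std::array<int, 2>& a, const std::array<int, 2>& b) {
                     int ra = a[0] * a[0] + a[1] * a[1];
                     int rb = b[0] * b[0] + b[1] * b[1];
                     if (ra != rb) return ra < rb;
                     if (a[1] != b[1]) return a[1] < b[1];
                     return a[0] < b[0];
                   });

  NumericMatrix out(np, 8);  // score, ref, psi_idx, dx, dy, psi_sub, dxs, dys
  std::vector<double> G((size_t)nref * 2 * nf);
  std::vector<double> curves((size_t)nref * ntheta);
  std::vector<double> bestcurve(ntheta);
  const double one = 1.0, zero = 0.0;
  const int twonf = 2 * nf;

  for (int p = 0; p < np; ++p) {
    const double* pimg = &particles[0] + (size_t)p * nx * ny;
    double bscore = -2.0;
    int bref = -1, bk = 0, bdx = 0, bdy = 0;
    bool any = false;
    for (size_t si = 0; si < shifts.size(); ++si) {
      int dx = shifts[si][0], dy = shifts[si][1];
      if (!polar_sample(pimg, nx, ny, P, dx, dy, S)) continue;
      ring_dft(P, S, FA, FB);
      // G(rf, f) = sum_r P(f, r) * conj(R_rf(f, r)), split re/im
      std::fill(G.begin(), G.end(), 0.0);
      for (int rf = 0; rf < nref; ++rf) {
        if (!refok[rf]) continue;
        const double* ra = &rA[rf * spec_sz];
        const double* rb = &rB[rf * spec_sz];
        for (int r = 0; r < nr; ++r) {
          const double* pa = &FA[(size_t)r * nf];
          const double* pb = &FB[(size_t)r * nf];
          const double* qa = ra + (size_t)r * nf;
          const double* qb = rb + (size_t)r * nf;
          for (int f = 0; f < nf; ++f) {
            G[(size_t)f * nref + rf] += pa[f] * qa[f] + pb[f] * qb[f];
            G[(size_t)(nf + f) * nref + rf] += pb[f] * qa[f] - pa[f] * qb[f];
          }
        }
      }
      // curves(rf, k) = G(rf, :) . inv(:, k)
      F77_CALL(dgemm)("N", "N", &nref, &ntheta, const_cast<int*>(&twonf),
                      &one, G.data(), &nref, P.inv.data(), &twonf, &zero,
                      curves.data(), &nref FCONE FCONE);
      for (int rf = 0; rf < nref; ++rf) {
        if (!refok[rf]) continue;
        for (int k = 0; k < ntheta; ++k) {
          double sc = curves[(size_t)k * nref + rf];
          bool better = sc > bscore;
          if (!better && sc == bscore) {
            // tie-break: lowest ref, then smallest psi, then smallest |delta|
            if (rf < bref || (rf == bref && k < bk)) better = true;
          }
          if (better) {
            bscore = sc;
            bref = rf;
            bk = k;
            bdx = dx;
            bdy = dy;
            for (int kk = 0; kk < ntheta; ++kk)
              bestcurve[kk] = curves[(size_t)kk * nref + rf];
            any = true;
          }
        }
      }
    }
    if (!any) {  // flat particle: no finite-variance patch anywhere
      out(p, 0) = 0.0;
      out(p, 1) = -1;
      continue;
    }
    // parabolic sub-grid refinement in psi (circular)
    double cm = bestcurve[(bk - 1 + ntheta) % ntheta];
    double c0 = bestcurve[bk];
    double cp = bestcurve[(bk + 1) % ntheta];
    double denom = cm - 2 * c0 + cp;
    double dpsi = (std::abs(denom) > 1e-12) ? 0.5 * (cm - cp) / denom : 0.0;
    if (dpsi > 0.5) dpsi = 0.5;
    if (dpsi < -0.5) dpsi = -0.5;
    // parabolic sub-pixel refinement in shift at (bref, bk)
    double sxm = bscore, sxp = bscore, sym = bscore, syp = bscore;
    const double* rs = &rsamp[(size_t)bref * nr * ntheta];
    auto score_at = [&](double ddx, double ddy) -> double {
      if (!polar_sample(pimg, nx, ny, P, ddx, ddy, S)) return bscore;
      return lag_corr(P, S, rs, bk);
    };
    if (std::abs(bdx) < shift_max) {
      sxm = score_at(bdx - 1, bdy);
      sxp = score_at(bdx + 1, bdy);
    }
    if (std::abs(bdy) < shift_max) {
      sym = score_at(bdx, bdy - 1);
      syp = score_at(bdx, bdy + 1);
    }
    auto para = [](double m, double c, double p) -> double {
      double d = m - 2 * c + p;
      if (std::abs(d) < 1e-12) return 0.0;
      double s = 0.5 * (m - p) / d;
      if (s > 0.5) s = 0.5;
      if (s < -0.5) s = -0.5;
      return s;
    };
    out(p, 0) = bscore;
    out(p, 1) = bref;
    out(p, 2) = bk;
    out(p, 3) = bdx;
    out(p, 4) = bdy;
    out(p, 5) = dpsi;
    out(p, 6) = (sxm != bscore || sxp != bscore) ? para(sxm, bscore, sxp) : 0.0;
    out(p, 7) = (sym != bscore || syp != bscore) ? para(sym, bscore, syp) : 0.0;
  }
  return out;
}

// 6-connected component labelling of a logical 3D mask
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int iz = q / ((size_t)nx * ny);
      int rem = q - (size_t)iz * nx * ny;
      int iy = rem / nx, ix = rem % nx;
      const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                             {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      for (int d = 0; d < 6; ++d) {
        int jx = ix + off[d][0], jy = iy + off[d][1], jz = iz + off[d][2];
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
          continue;
        size_t t = ((size_t)jz * ny + jy) * nx + jx;
        if (mask[t] && !lab[t]) {
          lab[t] = cur;
          stack.push_back(t);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
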