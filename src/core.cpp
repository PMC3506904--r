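// Core numerics: in-plane rotation, separable Gaussian diffusion, the
// rotation-based forward/back projector with incremental attenuation, and
// the forced-detection Monte Carlo engine for scatter estimation.
//
// Conventions:
//  - volumes are column-major R arrays (nx, ny, nz); index x + nx*(y + ny*z)
//  - projections are (nu, nv, nview) with u along x, v along z
//  - for view angle A the volume is resampled in-plane so that the detector
//    normal is +y; plane y = 0 is farthest from the detector
//  - detector pixel size equals the in-plane voxel size (enforced in R)

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double ELECTRON_REST_KEV = 511.0;
static const double FWHM_TO_SIGMA = 2.3548200450309493; // 2*sqrt(2*log(2))
static const double BLUR_PENDING_THRESH = 0.15;         // px^2

// ---------------------------------------------------------------------------
// Gaussian kernels and separable blurs
// ---------------------------------------------------------------------------

// Discrete symmetric kernel whose second moment equals var_px2 exactly.
// Small variances use a three-tap kernel; larger ones a bin-integrated
// Gaussian whose width is tuned by fixed-point iteration so the discrete
// variance matches the target (Sheppard-style corrections are inaccurate
// for sub-pixel sigmas).
static std::vector<double> gauss_kernel(double var_px2) {
  if (var_px2 <= 1e-9) return std::vector<double>(1, 1.0);
  if (var_px2 <= 0.25) {
    std::vector<double> k(3);
    k[0] = k[2] = var_px2 / 2.0;
    k[1] = 1.0 - var_px2;
    return k;
  }
  int radius = (int)std::ceil(4.0 * std::sqrt(var_px2)) + 2;
  std::vector<double> k(2 * radius + 1);
  double vc = var_px2;
  for (int iter = 0; iter < 30; ++iter) {
    double s2 = std::sqrt(2.0 * vc), sum = 0.0, mom = 0.0;
    for (int i = -radius; i <= radius; ++i) {
      double v = 0.5 * (std::erf((i + 0.5) / s2) - std::erf((i - 0.5) / s2));
      k[i + radius] = v;
      sum += v;
      mom += v * i * i;
    }
    for (double& v : k) v /= sum;
    mom /= sum;
    if (std::fabs(mom - var_px2) < 1e-9 * var_px2) break;
    vc *= var_px2 / mom;
    if (vc < 1e-12) vc = 1e-12;
  }
  return k;
}

// 1-D convolution along a strided axis, zero boundary; kernel symmetric.
static void conv1d_strided(std::vector<double>& buf, double* img, int n,
                           int stride, const std::vector<double>& k) {
  int radius = ((int)k.size() - 1) / 2;
  if (radius == 0) return;
  buf.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = img[(size_t)i * stride];
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    int j0 = std::max(0, i - radius), j1 = std::min(n - 1, i + radius);
    for (int j = j0; j <= j1; ++j) acc += buf[j] * k[(j - i) + radius];
    img[(size_t)i * stride] = acc;
  }
}

// separable 2-D blur of an (nx, nz) image stored with x contiguous
static void blur2d(double* img, int nx, int nz, const std::vector<double>& k,
                   std::vector<double>& scratch) {
  if (k.size() == 1) return;
  for (int z = 0; z < nz; ++z)
    conv1d_strided(scratch, img + (size_t)z * nx, nx, 1, k);
  for (int x = 0; x < nx; ++x)
    conv1d_strided(scratch, img + x, nz, nx, k);
}

// ---------------------------------------------------------------------------
// In-plane rotation (gather) and its exact adjoint (scatter)
// ---------------------------------------------------------------------------

static void snap_trig(double angle_deg, double& c, double& s) {
  double r = angle_deg / 90.0;
  double k = std::round(r);
  if (std::fabs(r - k) < 1e-9) {
    int m = ((int)k % 4 + 4) % 4;
    const double cs[4] = {1, 0, -1, 0}, sn[4] = {0, 1, 0, -1};
    c = cs[m]; s = sn[m];
  } else {
    double a = angle_deg * M_PI / 180.0;
    c = std::cos(a); s = std::sin(a);
  }
}

// Rotate in-plane by angle_deg (content rotated by -angle in the gather
// sense: output(x,y) samples input at center + R(angle)*(x-c, y-c)).
// adjoint = transpose of the same linear map (scatter with equal weights).
static void rotate_inplane(const double* src, double* dst,
                           int nx, int ny, int nz,
                           double angle_deg, bool adjoint) {
  double ca, sa;
  snap_trig(angle_deg, ca, sa);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  std::fill(dst, dst + (size_t)nx * ny * nz, 0.0);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double xs = cx + ca * (x - cx) - sa * (y - cy);
      double ys = cy + sa * (x - cx) + ca * (y - cy);
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double wx = xs - x0, wy = ys - y0;
      int xs_i[2] = {x0, x0 + 1}, ys_i[2] = {y0, y0 + 1};
      double wxs[2] = {1.0 - wx, wx}, wys[2] = {1.0 - wy, wy};
      for (int iy = 0; iy < 2; ++iy) {
        if (ys_i[iy] < 0 || ys_i[iy] >= ny || wys[iy] == 0.0) continue;
        for (int ix = 0; ix < 2; ++ix) {
          if (xs_i[ix] < 0 || xs_i[ix] >= nx || wxs[ix] == 0.0) continue;
          double w = wxs[ix] * wys[iy];
          size_t o = (size_t)x + (size_t)nx * y;
          size_t si = (size_t)xs_i[ix] + (size_t)nx * ys_i[iy];
          for (int z = 0; z < nz; ++z) {
            size_t pz = (size_t)nx * ny * z;
            if (!adjoint) dst[o + pz] += w * src[si + pz];
            else          dst[si + pz] += w * src[o + pz];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_rotate(NumericVector vol, IntegerVector dim,
                         double angle_deg, bool adjoint) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  rotate_inplane(vol.begin(), out.begin(), nx, ny, nz, angle_deg, adjoint);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Rotation-based projector with incremental diffusion and attenuation
// ---------------------------------------------------------------------------

struct BlurSchedule {
  // blur variance (px^2) applied immediately before processing plane j
  std::vector<double> before_plane;
  double final_var;
};

static BlurSchedule make_schedule(int ny, double radius_mm, double voxel_mm,
                                  double fwhm0_mm, double slope) {
  BlurSchedule s;
  s.before_plane.assign(ny, 0.0);
  double cy = 0.5 * (ny - 1);
  auto var_at = [&](int j) {
    double d = radius_mm - (j - cy) * voxel_mm; // plane j -> collimator face
    if (d < 0) d = 0;
    double sig = (fwhm0_mm + slope * d) / FWHM_TO_SIGMA / voxel_mm;
    return sig * sig;
  };
  double pending = 0.0;
  for (int j = 0; j < ny; ++j) {
    if (j > 0) {
      double dv = var_at(j - 1) - var_at(j);
      if (dv > 0) pending += dv;
    }
    if (pending >= BLUR_PENDING_THRESH) {
      s.before_plane[j] = pending;
      pending = 0.0;
    }
  }
  s.final_var = pending + var_at(ny - 1);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector input, NumericVector mu,
                          IntegerVector dim, NumericVector angles_deg,
                          double radius_mm, double voxel_mm,
                          double fwhm0_mm, double slope, bool forward) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nview = angles_deg.size();
  size_t nvox = (size_t)nx * ny * nz, nplane = (size_t)nx * nz;
  double step_cm = voxel_mm / 10.0;
  BlurSchedule sched = make_schedule(ny, radius_mm, voxel_mm, fwhm0_mm, slope);
  std::vector<std::vector<double>> kern(ny);
  for (int j = 0; j < ny; ++j)
    if (sched.before_plane[j] > 0) kern[j] = gauss_kernel(sched.before_plane[j]);
  std::vector<double> kfin = gauss_kernel(sched.final_var);

  std::vector<double> rin(nvox), rmu(nvox), acc(nplane), scratch;
  std::vector<double> rgrad;
  NumericVector out(forward ? nplane * nview : nvox);

  for (int v = 0; v < nview; ++v) {
    rotate_inplane(mu.begin(), rmu.data(), nx, ny, nz, angles_deg[v], false);
    if (forward) {
      rotate_inplane(input.begin(), rin.data(), nx, ny, nz, angles_deg[v], false);
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int j = 0; j < ny; ++j) {
        if (!kern[j].empty()) blur2d(acc.data(), nx, nz, kern[j], scratch);
        for (int z = 0; z < nz; ++z) {
          size_t po = (size_t)z * nx;
          size_t pv = (size_t)nx * (j + (size_t)ny * z);
          for (int x = 0; x < nx; ++x) {
            double t = std::exp(-rmu[pv + x] * step_cm);
            acc[po + x] = acc[po + x] * t + rin[pv + x] * std::sqrt(t);
          }
        }
      }
      blur2d(acc.data(), nx, nz, kfin, scratch);
      std::copy(acc.begin(), acc.end(), out.begin() + (size_t)v * nplane);
    } else {
      // exact adjoint: reverse every forward operation
      std::copy(input.begin() + (size_t)v * nplane,
                input.begin() + (size_t)(v + 1) * nplane, acc.begin());
      blur2d(acc.data(), nx, nz, kfin, scratch);
      rgrad.assign(nvox, 0.0);
      for (int j = ny - 1; j >= 0; --j) {
        for (int z = 0; z < nz; ++z) {
          size_t po = (size_t)z * nx;
          size_t pv = (size_t)nx * (j + (size_t)ny * z);
          for (int x = 0; x < nx; ++x) {
            double t = std::exp(-rmu[pv + x] * step_cm);
            rgrad[pv + x] = acc[po + x] * std::sqrt(t);
            acc[po + x] *= t;
          }
        }
        if (!kern[j].empty()) blur2d(acc.data(), nx, nz, kern[j], scratch);
      }
      rotate_inplane(rgrad.data(), rin.data(), nx, ny, nz, angles_deg[v], true);
      for (size_t i = 0; i < nvox; ++i) out[i] += rin[i];
    }
  }
  if (forward) out.attr("dim") = IntegerVector::create(nx, nz, nview);
  else out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3-D Gaussian post-filter and per-view blur
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma_px) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  if (sigma_px <= 0) { out.attr("dim") = dim; return out; }
  std::vector<double> k = gauss_kernel(sigma_px * sigma_px);
  std::vector<double> scratch;
  double* p = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      conv1d_strided(scratch, p + (size_t)nx * (y + (size_t)ny * z), nx, 1, k);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      conv1d_strided(scratch, p + x + (size_t)nx * ny * z, ny, nx, k);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      conv1d_strided(scratch, p + x + (size_t)nx * y, nz, nx * ny, k);
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_blur_views(NumericVector proj, IntegerVector dim,
                             double var_px2) {
  int nu = dim[0], nv = dim[1], nview = dim[2];
  NumericVector out = clone(proj);
  if (var_px2 <= 0) { out.attr("dim") = dim; return out; }
  std::vector<double> k = gauss_kernel(var_px2);
  std::vector<double> scratch;
  for (int v = 0; v < nview; ++v)
    blur2d(out.begin() + (size_t)v * nu * nv, nu, nv, k, scratch);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Klein-Nishina sampling
// ---------------------------------------------------------------------------

// normalised KN phase function over cos(theta); f(1) = 1
static inline double kn_shape(double u, double alpha) {
  double eps = 1.0 / (1.0 + alpha * (1.0 - u));
  return 0.5 * eps * eps * (eps + 1.0 / eps - (1.0 - u * u));
}

// total KN cross-section in units of 2*pi*r_e^2
static double kn_total(double energy_kev) {
  double a = energy_kev / ELECTRON_REST_KEV;
  double l = std::log(1 + 2 * a);
  return (1 + a) / (a * a) * (2 * (1 + a) / (1 + 2 * a) - l / a) +
         l / (2 * a) - (1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a));
}

static double sample_kn_cos(double alpha) {
  for (;;) {
    double u = 2.0 * unif_rand() - 1.0;
    if (unif_rand() <= kn_shape(u, alpha)) return u;
  }
}

// [[Rcpp::export]]
NumericVector cpp_sample_kn(int n, double energy_kev) {
  RNGScope scope;
  double alpha = energy_kev / ELECTRON_REST_KEV;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::acos(sample_kn_cos(alpha));
  return out;
}

// ---------------------------------------------------------------------------
// Forced-detection Monte Carlo scatter engine (coarse grid)
// ---------------------------------------------------------------------------

struct WinTable {
  // acceptance probability tabulated over energy, 0.25 keV steps
  double e0, de;
  std::vector<double> p;
  double lookup(double e) const {
    double x = (e - e0) / de;
    if (x <= 0) return p.front();
    if (x >= (double)(p.size() - 1)) return p.back();
    int i = (int)x; double f = x - i;
    return p[i] * (1 - f) + p[i + 1] * f;
  }
};

static WinTable make_wintable(double lo, double hi, double eres140) {
  WinTable t; t.e0 = 10.0; t.de = 0.25;
  int n = (int)((200.0 - t.e0) / t.de) + 1;
  t.p.resize(n);
  for (int i = 0; i < n; ++i) {
    double e = t.e0 + i * t.de;
    if (eres140 <= 0) {
      t.p[i] = (e >= lo && e <= hi) ? 1.0 : 0.0;
    } else {
      double sigma = eres140 * std::sqrt(140.0 * e) / FWHM_TO_SIGMA;
      t.p[i] = 0.5 * (std::erf((hi - e) / (sigma * std::sqrt(2.0))) -
                      std::erf((lo - e) / (sigma * std::sqrt(2.0))));
    }
  }
  return t;
}

// per-view transmission maps on the rotated coarse grid: exp(-line integral
// of mu from the voxel to the detector at a fixed evaluation energy).
// Stored as float, z-major per view so one (x', y') slab is contiguous.
static void make_transmission(const std::vector<double>& muE, int nx, int ny,
                              int nz, double step_cm,
                              const NumericVector& angles_deg,
                              std::vector<std::vector<float>>& T) {
  int nview = angles_deg.size();
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> rmu(nvox);
  T.assign(nview, std::vector<float>(nvox));
  for (int v = 0; v < nview; ++v) {
    rotate_inplane(muE.data(), rmu.data(), nx, ny, nz, angles_deg[v], false);
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) {
        double cum = 0.0; // from the near (detector, y = ny-1) side inward
        for (int j = ny - 1; j >= 0; --j) {
          size_t i = (size_t)x + (size_t)nx * (j + (size_t)ny * z);
          // layout: x + nx*j within the slab, slab per z
          T[v][(size_t)nx * ny * z + (size_t)nx * j + x] =
            (float)std::exp(-(cum + 0.5 * rmu[i]) * step_cm);
          cum += rmu[i];
        }
      }
    }
  }
}

// in-plane bilinear lookup at the nearest z slab (the scatter estimate is
// coarse-grained by construction; z interpolation does not change it
// measurably but costs a second slab of cache traffic)
static inline double slab_bilin(const float* slab, int nx, int ny,
                                double x, double y) {
  if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
  int x0 = (int)x, y0 = (int)y;
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  double fx = x - x0, fy = y - y0;
  const float* p = slab + (size_t)nx * y0 + x0;
  double c0 = p[0] + fx * (p[1] - p[0]);
  double c1 = p[nx] + fx * (p[nx + 1] - p[nx]);
  return c0 + fy * (c1 - c0);
}

static inline void deposit_bilinear(double* img, int nu, int nv,
                                    double u, double vv, double w) {
  int u0 = (int)std::floor(u), v0 = (int)std::floor(vv);
  double fu = u - u0, fv = vv - v0;
  for (int dv = 0; dv < 2; ++dv) {
    int vi = v0 + dv; if (vi < 0 || vi >= nv) continue;
    double wv = dv ? fv : 1 - fv;
    for (int du = 0; du < 2; ++du) {
      int ui = u0 + du; if (ui < 0 || ui >= nu) continue;
      double wu = du ? fu : 1 - fu;
      img[(size_t)ui + (size_t)nu * vi] += w * wu * wv;
    }
  }
}

// [[Rcpp::export]]
List cpp_mc_scatter(NumericVector act, NumericVector muC_ref,
                    NumericVector muP_ref, IntegerVector dim,
                    double voxel_mm, NumericVector angles_deg,
                    double emission_kev, double n_photons, int max_order,
                    double scat_lo, double scat_hi,
                    double emis_lo, double emis_hi,
                    double eres140, double exit_scat_kev) {
  RNGScope scope;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nview = angles_deg.size();
  size_t nvox = (size_t)nx * ny * nz, nbin = (size_t)nx * nz;
  double step_cm = voxel_mm / 10.0;
  double kn_ref = kn_total(140.0);

  // energy scaling of the reference (140 keV) attenuation components
  auto fC = [&](double e) { return kn_total(e) / kn_ref; };
  auto fP = [&](double e) { return (140.0 / e) * (140.0 / e) * (140.0 / e); };

  // emission CDF
  std::vector<double> cdf(nvox);
  double tot = 0.0;
  for (size_t i = 0; i < nvox; ++i) { tot += std::max(act[i], 0.0); cdf[i] = tot; }
  NumericVector scat((size_t)nbin * nview), prim((size_t)nbin * nview);
  scat.attr("dim") = IntegerVector::create(nx, nz, nview);
  prim.attr("dim") = IntegerVector::create(nx, nz, nview);
  if (tot <= 0 || n_photons < 1) return List::create(_["scatter"] = scat,
                                                     _["primary"] = prim);
  for (size_t i = 0; i < nvox; ++i) cdf[i] /= tot;

  double muC_max = *std::max_element(muC_ref.begin(), muC_ref.end());
  double muP_max = *std::max_element(muP_ref.begin(), muP_ref.end());

  // transmission maps: scatter exits evaluated at the scoring-window centre,
  // primaries at the emission energy
  std::vector<double> muE(nvox);
  std::vector<std::vector<float>> Tscat, Tprim;
  for (size_t i = 0; i < nvox; ++i)
    muE[i] = muC_ref[i] * fC(exit_scat_kev) + muP_ref[i] * fP(exit_scat_kev);
  make_transmission(muE, nx, ny, nz, step_cm, angles_deg, Tscat);
  for (size_t i = 0; i < nvox; ++i)
    muE[i] = muC_ref[i] * fC(emission_kev) + muP_ref[i] * fP(emission_kev);
  make_transmission(muE, nx, ny, nz, step_cm, angles_deg, Tprim);

  WinTable win_scat = make_wintable(scat_lo, scat_hi, eres140);
  WinTable win_emis = make_wintable(emis_lo, emis_hi, eres140);
  double p_emis0 = win_emis.lookup(emission_kev);

  // per-view detector frame: rotated x' = c + ca*(x-c) + sa*(y-c)
  std::vector<double> vca(nview), vsa(nview), dvx(nview), dvy(nview);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int v = 0; v < nview; ++v) {
    double ca, sa; snap_trig(angles_deg[v], ca, sa);
    vca[v] = ca; vsa[v] = sa;
    dvx[v] = -sa; dvy[v] = ca; // detector normal in original coordinates
  }

  long long nph = (long long)n_photons;
  for (long long ph = 0; ph < nph; ++ph) {
    // emission site (continuous, voxel units)
    double r = unif_rand();
    size_t lo = 0, hi = nvox - 1;
    while (lo < hi) { size_t mid = (lo + hi) / 2; if (cdf[mid] < r) lo = mid + 1; else hi = mid; }
    size_t vx = lo;
    int ex = vx % nx, ey = (vx / nx) % ny, ez = vx / ((size_t)nx * ny);
    double px = ex + unif_rand() - 0.5;
    double py = ey + unif_rand() - 0.5;
    double pz = ez + unif_rand() - 0.5;

    // primary (order 0) forced detection
    {
      int zs = (int)(pz + 0.5);
      if (zs < 0) zs = 0; else if (zs > nz - 1) zs = nz - 1;
      size_t zoff = (size_t)nx * ny * zs;
      double w0 = p_emis0 / (4.0 * M_PI);
      for (int v = 0; v < nview; ++v) {
        double xr = cx + vca[v] * (px - cx) + vsa[v] * (py - cy);
        double yr = cy - vsa[v] * (px - cx) + vca[v] * (py - cy);
        double T = slab_bilin(Tprim[v].data() + zoff, nx, ny, xr, yr);
        deposit_bilinear(&prim[(size_t)v * nbin], nx, nz, xr, pz, T * w0);
      }
    }

    // isotropic initial direction
    double uz = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double dx = st * std::cos(phi), dy = st * std::sin(phi), dz = uz;
    double E = emission_kev, w = 1.0;

    for (int order = 1; order <= max_order; ++order) {
      // Woodcock tracking to the next real interaction
      double mu_max = muC_max * fC(E) + muP_max * fP(E);
      bool interacted = false;
      while (true) {
        double s = -std::log(unif_rand()) / (mu_max * step_cm); // voxel units
        px += dx * s; py += dy * s; pz += dz * s;
        if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 ||
            pz < 0 || pz > nz - 1) break; // escaped
        size_t i = (size_t)(int)(px + 0.5) + (size_t)nx *
                   ((size_t)(int)(py + 0.5) + (size_t)ny * (size_t)(int)(pz + 0.5));
        double muC = muC_ref[i] * fC(E), muP = muP_ref[i] * fP(E);
        if (unif_rand() < (muC + muP) / mu_max) {
          // real interaction: photoelectric absorbs, Compton scatters
          if (unif_rand() < muP / (muC + muP)) break; // absorbed
          interacted = true;
          break;
        }
      }
      if (!interacted) break;

      // forced detection: expected contribution of this scatter to each view
      double alpha = E / ELECTRON_REST_KEV;
      double norm = kn_total(E); // integral of kn_shape over cos(theta)
      double knc = w / (2.0 * M_PI * norm);
      int zs = (int)(pz + 0.5);
      if (zs < 0) zs = 0; else if (zs > nz - 1) zs = nz - 1;
      size_t zoff = (size_t)nx * ny * zs;
      for (int v = 0; v < nview; ++v) {
        double cth = dx * dvx[v] + dy * dvy[v]; // dz * 0
        double Eprime = E / (1.0 + alpha * (1.0 - cth));
        double pacc = win_scat.lookup(Eprime);
        if (pacc <= 1e-12) continue;
        // pdf per steradian of scattering towards the detector direction
        double xr = cx + vca[v] * (px - cx) + vsa[v] * (py - cy);
        double yr = cy - vsa[v] * (px - cx) + vca[v] * (py - cy);
        double T = slab_bilin(Tscat[v].data() + zoff, nx, ny, xr, yr);
        deposit_bilinear(&scat[(size_t)v * nbin], nx, nz, xr, pz,
                         knc * kn_shape(cth, alpha) * T * pacc);
      }

      // sample the actual scattering for continued transport
      double cth = sample_kn_cos(alpha);
      double Enew = E / (1.0 + alpha * (1.0 - cth));
      double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
      double psi = 2.0 * M_PI * unif_rand();
      // rotate direction by (theta, psi) about current direction
      double ax, ay, az;
      if (std::fabs(dz) < 0.99) { ax = -dy; ay = dx; az = 0.0; }
      else { ax = 1.0; ay = 0.0; az = 0.0; }
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      ax /= an; ay /= an; az /= an;
      double bx = dy * az - dz * ay, by = dz * ax - dx * az, bz = dx * ay - dy * ax;
      double ndx = cth * dx + sth * (std::cos(psi) * ax + std::sin(psi) * bx);
      double ndy = cth * dy + sth * (std::cos(psi) * ay + std::sin(psi) * by);
      double ndz = cth * dz + sth * (std::cos(psi) * az + std::sin(psi) * bz);
      double nn = std::sqrt(ndx * ndx + ndy * ndy + ndz * ndz);
      dx = ndx / nn; dy = ndy / nn; dz = ndz / nn;
      E = Enew;
      // Russian roulette guard for very low weights
      if (w < 1e-4) {
        if (unif_rand() < 0.1) w *= 10.0; else break;
      }
    }
  }
  return List::create(_["scatter"] = scat, _["primary"] = prim);
}
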