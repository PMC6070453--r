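#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rotation-based parallel-beam projector. The detector sits on the +y side of
// the rotated frame; fp_angle and bp_angle are exact transposes of each other
// (bilinear gather vs scatter with identical weights, symmetric zero-padded
// blur kernels, shared diagonal attenuation), which is what makes the MLEM
// likelihood monotone.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Rotate a volume about the z axis by theta (radians), bilinear per z-slice.
// adjoint = true applies the exact transpose of the forward interpolation.
static std::vector<double> rotate_z_core(const double *vol, int nx, int ny,
                                         int nz, double theta, bool adjoint) {
  const size_t npix = (size_t)nx * ny;
  std::vector<double> out(npix * nz, 0.0);
  const double c = std::cos(theta), s = std::sin(theta);
  const double xc = 0.5 * (nx - 1), yc = 0.5 * (ny - 1);
  // precompute the (up to 4) in-bounds neighbour offsets + weights per pixel
  std::vector<int> nnb(npix, 0);
  std::vector<int> noff(npix * 4);
  std::vector<double> nw(npix * 4);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const size_t p = i + (size_t)nx * j;
      const double u = i - xc, v = j - yc;
      const double xs = c * u + s * v + xc;
      const double ys = -s * u + c * v + yc;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      const int xi[2] = {x0, x0 + 1};
      const int yi[2] = {y0, y0 + 1};
      const double wx[2] = {1.0 - fx, fx};
      const double wy[2] = {1.0 - fy, fy};
      int m = 0;
      for (int a = 0; a < 2; ++a) {
        if (xi[a] < 0 || xi[a] >= nx) continue;
        for (int b = 0; b < 2; ++b) {
          if (yi[b] < 0 || yi[b] >= ny) continue;
          const double w = wx[a] * wy[b];
          if (w == 0.0) continue;
          noff[p * 4 + m] = xi[a] + nx * yi[b];
          nw[p * 4 + m] = w;
          ++m;
        }
      }
      nnb[p] = m;
    }
  }
  // apply slice by slice (cache friendly)
  for (int k = 0; k < nz; ++k) {
    const double *in_k = vol + npix * k;
    double *out_k = out.data() + npix * k;
    for (size_t p = 0; p < npix; ++p) {
      const int m = nnb[p];
      if (!adjoint) {
        double acc = 0.0;
        for (int t = 0; t < m; ++t) acc += nw[p * 4 + t] * in_k[noff[p * 4 + t]];
        out_k[p] = acc;
      } else {
        const double v = in_k[p];
        if (v != 0.0) {
          for (int t = 0; t < m; ++t) out_k[noff[p * 4 + t]] += nw[p * 4 + t] * v;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".rotate_z")]]
NumericVector rotate_z(NumericVector vol, IntegerVector dim, double theta,
                       bool adjoint) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> out =
      rotate_z_core(REAL(vol), nx, ny, nz, theta, adjoint);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dim;
  return res;
}

static std::vector<double> gauss_kernel(double sigma_px) {
  if (sigma_px < 0.05) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.5 * sigma_px);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double sum = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma_px * sigma_px));
    sum += k[t + r];
  }
  for (double &v : k) v /= sum;
  return k;
}

// in-place separable convolution of an nx x nz slab, zero padding
static void blur_slab(std::vector<double> &S, int nx, int nz,
                      const std::vector<double> &ker) {
  const int r = ((int)ker.size() - 1) / 2;
  if (r == 0) return;
  std::vector<double> tmp((size_t)nx * nz, 0.0);
  // along x
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      double acc = 0.0;
      const int lo = std::max(0, i - r), hi = std::min(nx - 1, i + r);
      for (int t = lo; t <= hi; ++t) acc += ker[t - i + r] * S[t + nx * k];
      tmp[i + nx * k] = acc;
    }
  }
  // along z
  for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) {
      double acc = 0.0;
      const int lo = std::max(0, k - r), hi = std::min(nz - 1, k + r);
      for (int t = lo; t <= hi; ++t) acc += ker[t - k + r] * tmp[i + nx * t];
      S[i + nx * k] = acc;
    }
  }
}

// attenuation factors in the rotated frame: detector at +y (large j)
static std::vector<double> att_factors(const std::vector<double> &mur, int nx,
                                       int ny, int nz, double vox_cm) {
  std::vector<double> att((size_t)nx * ny * nz);
  std::vector<double> cum(nx);
  for (int k = 0; k < nz; ++k) {
    std::fill(cum.begin(), cum.end(), 0.0);
    for (int j = ny - 1; j >= 0; --j) {
      const size_t row = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        const double m = mur[row + i];
        att[row + i] = std::exp(-vox_cm * (cum[i] + 0.5 * m));
        cum[i] += m;
      }
    }
  }
  return att;
}

static double depth_sigma_px(int j, int ny, double vox_mm, double orbit_mm,
                             double psf_int_mm, double psf_slope) {
  const double yw = (j - 0.5 * (ny - 1)) * vox_mm;
  const double d = orbit_mm - yw; // distance to the detector plane
  const double fwhm =
      std::sqrt(psf_int_mm * psf_int_mm + psf_slope * d * psf_slope * d);
  return fwhm / (2.354820045 * vox_mm);
}

// [[Rcpp::export(name = ".fp_angle")]]
NumericMatrix fp_angle(NumericVector act, NumericVector mu, IntegerVector dim,
                       double theta, double vox_mm, double sens_time,
                       double orbit_mm, double psf_int_mm, double psf_slope,
                       bool use_psf, bool use_att) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // scatter-form rotation of the emitters: conserves total activity exactly
  std::vector<double> actr =
      rotate_z_core(REAL(act), nx, ny, nz, -theta, true);
  std::vector<double> att;
  if (use_att) {
    // gather-form (interpolating) rotation keeps the mu map smooth
    std::vector<double> mur = rotate_z_core(REAL(mu), nx, ny, nz, theta, false);
    att = att_factors(mur, nx, ny, nz, vox_mm / 10.0);
  }
  NumericMatrix proj(nx, nz);
  std::vector<double> slab((size_t)nx * nz);
  for (int j = 0; j < ny; ++j) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        double w = actr[idx3(i, j, k, nx, ny)];
        if (use_att) w *= att[idx3(i, j, k, nx, ny)];
        slab[i + nx * k] = w;
      }
    if (use_psf) {
      std::vector<double> ker = gauss_kernel(
          depth_sigma_px(j, ny, vox_mm, orbit_mm, psf_int_mm, psf_slope));
      blur_slab(slab, nx, nz, ker);
    }
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) proj(i, k) += slab[i + nx * k];
  }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) proj(i, k) *= sens_time;
  return proj;
}

// [[Rcpp::export(name = ".bp_angle")]]
NumericVector bp_angle(NumericMatrix proj, NumericVector mu, IntegerVector dim,
                       double theta, double vox_mm, double sens_time,
                       double orbit_mm, double psf_int_mm, double psf_slope,
                       bool use_psf, bool use_att) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> att;
  if (use_att) {
    std::vector<double> mur = rotate_z_core(REAL(mu), nx, ny, nz, theta, false);
    att = att_factors(mur, nx, ny, nz, vox_mm / 10.0);
  }
  std::vector<double> volr((size_t)nx * ny * nz, 0.0);
  std::vector<double> slab((size_t)nx * nz);
  for (int j = 0; j < ny; ++j) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) slab[i + nx * k] = proj(i, k);
    if (use_psf) {
      std::vector<double> ker = gauss_kernel(
          depth_sigma_px(j, ny, vox_mm, orbit_mm, psf_int_mm, psf_slope));
      blur_slab(slab, nx, nz, ker);
    }
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        double w = slab[i + nx * k] * sens_time;
        if (use_att) w *= att[idx3(i, j, k, nx, ny)];
        volr[idx3(i, j, k, nx, ny)] = w;
      }
  }
  // exact transpose of the scatter-form rotation used in fp_angle
  std::vector<double> vol =
      rotate_z_core(volr.data(), nx, ny, nz, -theta, false);
  NumericVector res(vol.begin(), vol.end());
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export(name = ".conv3_gauss")]]
NumericVector conv3_gauss(NumericVector vol, IntegerVector dim,
                          NumericVector sigma_px) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(REAL(vol), REAL(vol) + (size_t)nx * ny * nz);
  std::vector<double> b(a.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    std::vector<double> ker = gauss_kernel(sigma_px[ax]);
    const int r = ((int)ker.size() - 1) / 2;
    if (r == 0) continue;
    // iterate over lines along axis ax
    const int len = n[ax], st = stride[ax];
    const int oa1 = (ax + 1) % 3, oa2 = (ax + 2) % 3;
    for (int p = 0; p < n[oa1]; ++p) {
      for (int q = 0; q < n[oa2]; ++q) {
        const size_t base = (size_t)p * stride[oa1] + (size_t)q * stride[oa2];
        for (int t = 0; t < len; ++t) {
          double acc = 0.0;
          const int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
          for (int u = lo; u <= hi; ++u)
            acc += ker[u - t + r] * a[base + (size_t)u * st];
          b[base + (size_t)t * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export(name = ".conv2_gauss")]]
NumericMatrix conv2_gauss(NumericMatrix img, double sigma_px) {
  const int nx = img.nrow(), nz = img.ncol();
  std::vector<double> S((size_t)nx * nz);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) S[i + nx * k] = img(i, k);
  blur_slab(S, nx, nz, gauss_kernel(sigma_px));
  NumericMatrix out(nx, nz);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) out(i, k) = S[i + nx * k];
  return out;
}

// 6-connected component labelling of a binary volume
// [[Rcpp::export(name = ".label6")]]
IntegerVector label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int cur = 0;
  std::vector<size_t> stack;
  const int *m = LOGICAL(mask);
  for (size_t seed = 0; seed < nvox; ++seed) {
    if (m[seed] != 1 || lab[seed] != 0) continue;
    ++cur;
    stack.push_back(seed);
    lab[seed] = cur;
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      const int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t w = idx3(ii, jj, kk, nx, ny);
        if (m[w] == 1 && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
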