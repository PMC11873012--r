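// Low-level image kernels: separable Gaussian blur, affine warps, grating
// synthesis, bubble-mask rasterization, capsule rendering and im2col/maxpool
// for the convolutional forward pass. All images are column-major R matrices
// with values in [0, 1]; coordinates are 1-based at the R interface and
// converted here.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  return k;
}

// Separable Gaussian blur, reflect padding at the borders.
static void blur_inplace(std::vector<double> &img, int nr, int nc,
                         const std::vector<double> &k) {
  int r = ((int)k.size() - 1) / 2;
  std::vector<double> tmp(img.size());
  // along rows (within a column)
  for (int j = 0; j < nc; ++j) {
    const double *col = &img[(size_t)j * nr];
    double *out = &tmp[(size_t)j * nr];
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[d + r] * col[ii];
      }
      out[i] = acc;
    }
  }
  // along columns (across columns): accumulate whole columns so the
  // inner loops stay contiguous in memory
  for (int j = 0; j < nc; ++j) {
    double *out = &img[(size_t)j * nr];
    std::fill(out, out + nr, 0.0);
    for (int d = -r; d <= r; ++d) {
      int jj = j + d;
      if (jj < 0) jj = -jj - 1;
      if (jj >= nc) jj = 2 * nc - jj - 1;
      const double *src = &tmp[(size_t)jj * nr];
      double kv = k[d + r];
      for (int i = 0; i < nr; ++i) out[i] += kv * src[i];
    }
  }
}

// Fast seeded Gaussian generator (Marsaglia polar method on mt19937_64
// doubles); statistically standard normal, reproducible per seed.
struct FastNormal {
  std::mt19937_64 rng;
  double spare;
  bool has_spare;
  explicit FastNormal(uint64_t seed) : rng(seed), spare(0), has_spare(false) {}
  double unif() {
    return (rng() >> 11) * (1.0 / 9007199254740992.0) * 2.0 - 1.0;
  }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = unif();
      v = unif();
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_sep_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> buf(img.begin(), img.end());
  blur_inplace(buf, nr, nc, gauss_kernel(sigma));
  NumericMatrix out(nr, nc);
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_add_noise(NumericMatrix img, double sigma, int seed,
                            bool clip) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  FastNormal N((uint64_t)seed);
  for (R_xlen_t i = 0; i < img.size(); ++i) {
    double v = img[i] + (sigma > 0 ? sigma * N() : 0.0);
    if (clip) v = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    out[i] = v;
  }
  return out;
}

// Inverse-mapped affine warp: for each output pixel (x, y) in 0-based
// centered-at-origin-free coordinates, sample the input at
// (a11*x + a12*y + tx, a21*x + a22*y + ty). m = (a11,a21,a12,a22,tx,ty).
// Out-of-frame source pixels -> fill.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(NumericMatrix img, NumericVector m,
                              bool bilinear, double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double a11 = m[0], a21 = m[1], a12 = m[2], a22 = m[3], tx = m[4], ty = m[5];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      // x = column index, y = row index (0-based)
      double sx = a11 * j + a12 * i + tx;
      double sy = a21 * j + a22 * i + ty;
      double v = fill;
      if (bilinear) {
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        if (x0 >= -1 && x0 < nc && y0 >= -1 && y0 < nr) {
          double fx = sx - x0, fy = sy - y0;
          double acc = 0.0;
          for (int dy = 0; dy <= 1; ++dy) {
            for (int dx = 0; dx <= 1; ++dx) {
              int xx = x0 + dx, yy = y0 + dy;
              double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
              double pv = (xx >= 0 && xx < nc && yy >= 0 && yy < nr)
                              ? img[(size_t)xx * nr + yy]
                              : fill;
              acc += w * pv;
            }
          }
          v = acc;
        }
      } else {
        int xx = (int)std::lround(sx), yy = (int)std::lround(sy);
        if (xx >= 0 && xx < nc && yy >= 0 && yy < nr)
          v = img[(size_t)xx * nr + yy];
      }
      out[(size_t)j * nr + i] = v;
    }
  }
  return out;
}

// Sine grating: 0.5 + (c/2) * sin(2*pi*nu*u + phase), u in degrees along the
// orientation axis, u = (x*cos(theta) + y*sin(theta)) / ppd.
// [[Rcpp::export]]
NumericMatrix cpp_grating(int nr, int nc, double nu, double contrast,
                          double theta, double phase, double ppd) {
  NumericMatrix out(nr, nc);
  double ct = std::cos(theta), st = std::sin(theta);
  double w = 2.0 * M_PI * nu / ppd;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out[(size_t)j * nr + i] =
          0.5 + 0.5 * contrast * std::sin(w * (j * ct + i * st) + phase);
  return out;
}

static void patch_sd_one(const std::vector<double> &img, int nr, int nc,
                         int p, int off_r, int off_c, int grid_r, int grid_c,
                         double *out) {
  int q = 0;
  for (int gc = 0; gc < grid_c; ++gc) {
    for (int gr = 0; gr < grid_r; ++gr) {
      double s = 0.0, s2 = 0.0;
      for (int j = 0; j < p; ++j) {
        const double *col = &img[(size_t)(off_c + gc * p + j) * nr];
        for (int i = 0; i < p; ++i) {
          double v = col[off_r + gr * p + i];
          s += v;
          s2 += v * v;
        }
      }
      double n = (double)p * p;
      double var = s2 / n - (s / n) * (s / n);
      out[q++] = var > 0 ? std::sqrt(var) : 0.0;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_patch_sd(NumericMatrix img, int p, int off_r, int off_c,
                           int grid_r, int grid_c) {
  std::vector<double> buf(img.begin(), img.end());
  NumericVector out(grid_r * grid_c);
  patch_sd_one(buf, img.nrow(), img.ncol(), p, off_r, off_c, grid_r, grid_c,
               REAL(out));
  return out;
}

// Batch generator for the grating-detection observer: n trials with random
// orientation/phase and per-trial contrast, blurred then noised, reduced to
// patch-contrast features. Returns n x (grid_r*grid_c).
// [[Rcpp::export]]
NumericMatrix cpp_grating_features(int n, int nr, int nc, double nu,
                                   NumericVector contrasts, double ppd,
                                   double sigma_blur, double sigma_noise,
                                   int p, int off_r, int off_c, int grid_r,
                                   int grid_c, int seed) {
  NumericMatrix feat(n, grid_r * grid_c);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  FastNormal N((uint64_t)seed ^ 0x9e3779b97f4a7c15ULL);
  std::vector<double> img((size_t)nr * nc);
  std::vector<double> row(grid_r * grid_c);
  std::vector<double> k;
  if (sigma_blur > 0) k = gauss_kernel(sigma_blur);
  for (int t = 0; t < n; ++t) {
    double theta = U(rng) * M_PI;
    double phase = U(rng) * 2.0 * M_PI;
    double c = contrasts[t % contrasts.size()];
    double ct = std::cos(theta), st = std::sin(theta);
    double w = 2.0 * M_PI * nu / ppd;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        img[(size_t)j * nr + i] =
            0.5 + 0.5 * c * std::sin(w * (j * ct + i * st) + phase);
    if (sigma_blur > 0) blur_inplace(img, nr, nc, k);
    if (sigma_noise > 0)
      for (auto &v : img) {
        v += sigma_noise * N();
        v = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
      }
    patch_sd_one(img, nr, nc, p, off_r, off_c, grid_r, grid_c, row.data());
    for (int q = 0; q < (int)row.size(); ++q) feat(t, q) = row[q];
  }
  return feat;
}

// Same reduction for uniform mid-gray images (blur of a constant is the
// constant, so only noise is simulated).
// [[Rcpp::export]]
NumericMatrix cpp_gray_features(int n, int nr, int nc, double sigma_noise,
                                int p, int off_r, int off_c, int grid_r,
                                int grid_c, int seed) {
  NumericMatrix feat(n, grid_r * grid_c);
  FastNormal N((uint64_t)seed);
  std::vector<double> img((size_t)nr * nc);
  std::vector<double> row(grid_r * grid_c);
  for (int t = 0; t < n; ++t) {
    for (auto &v : img) {
      v = 0.5 + (sigma_noise > 0 ? sigma_noise * N() : 0.0);
      v = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
    patch_sd_one(img, nr, nc, p, off_r, off_c, grid_r, grid_c, row.data());
    for (int q = 0; q < (int)row.size(); ++q) feat(t, q) = row[q];
  }
  return feat;
}

// Psychometric features: n_base blurred unit sinusoid patterns, each scaled
// by every contrast in `contrasts` with fresh noise, features stacked as
// base-major blocks of length n_contrast. Row order: (base 1, c 1..K),
// (base 2, c 1..K), ...
// [[Rcpp::export]]
NumericMatrix cpp_psycho_features(int n_base, int nr, int nc, double nu,
                                  NumericVector contrasts, double ppd,
                                  double sigma_blur, double sigma_noise,
                                  int p, int off_r, int off_c, int grid_r,
                                  int grid_c, int seed) {
  int K = contrasts.size();
  NumericMatrix feat(n_base * K, grid_r * grid_c);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  FastNormal N((uint64_t)seed ^ 0x9e3779b97f4a7c15ULL);
  std::vector<double> base((size_t)nr * nc), img((size_t)nr * nc);
  std::vector<double> row(grid_r * grid_c);
  std::vector<double> k;
  if (sigma_blur > 0) k = gauss_kernel(sigma_blur);
  for (int b = 0; b < n_base; ++b) {
    double theta = U(rng) * M_PI;
    double phase = U(rng) * 2.0 * M_PI;
    double ct = std::cos(theta), st = std::sin(theta);
    double w = 2.0 * M_PI * nu / ppd;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        base[(size_t)j * nr + i] = std::sin(w * (j * ct + i * st) + phase);
    if (sigma_blur > 0) blur_inplace(base, nr, nc, k);
    for (int q = 0; q < K; ++q) {
      double c = contrasts[q];
      for (size_t z = 0; z < img.size(); ++z) {
        double v = 0.5 + 0.5 * c * base[z];
        if (sigma_noise > 0) v += sigma_noise * N();
        img[z] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
      }
      patch_sd_one(img, nr, nc, p, off_r, off_c, grid_r, grid_c, row.data());
      for (int q2 = 0; q2 < (int)row.size(); ++q2)
        feat(b * K + q, q2) = row[q2];
    }
  }
  return feat;
}

// Bubble masks: n masks over a size x size frame; nb Gaussian apertures of
// SD sigma with centers uniform in the centered square of side
// region_frac * size; mask = min(1, sum of apertures). Returns n x size^2
// (pixels in column-major order).
// [[Rcpp::export]]
NumericMatrix cpp_bubble_masks(int n, int nb, double sigma, int size,
                               double region_frac, int seed) {
  NumericMatrix out(n, (R_xlen_t)size * size);
  std::mt19937_64 rng((uint64_t)seed);
  double half = 0.5 * region_frac * size;
  double c0 = 0.5 * (size - 1);
  std::uniform_real_distribution<double> U(-half, half);
  int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> mask((size_t)size * size);
  for (int t = 0; t < n; ++t) {
    std::fill(mask.begin(), mask.end(), 0.0);
    for (int b = 0; b < nb; ++b) {
      double cx = c0 + U(rng), cy = c0 + U(rng);
      int jlo = std::max(0, (int)std::floor(cx) - r);
      int jhi = std::min(size - 1, (int)std::ceil(cx) + r);
      int ilo = std::max(0, (int)std::floor(cy) - r);
      int ihi = std::min(size - 1, (int)std::ceil(cy) + r);
      for (int j = jlo; j <= jhi; ++j) {
        double dx2 = (j - cx) * (j - cx);
        for (int i = ilo; i <= ihi; ++i) {
          double d2 = dx2 + (i - cy) * (i - cy);
          mask[(size_t)j * size + i] += std::exp(-d2 / (2.0 * sigma * sigma));
        }
      }
    }
    for (size_t z = 0; z < mask.size(); ++z)
      out(t, z) = mask[z] > 1.0 ? 1.0 : mask[z];
  }
  return out;
}

// Rasterize capsules (thick 2D segments): pixel gets `intensity` if its
// distance to any segment is <= the segment's radius. Segments are rows of
// (x1, y1, x2, y2, radius) in 0-based pixel coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_render_capsules(int nr, int nc, NumericMatrix seg,
                                  double intensity) {
  NumericMatrix out(nr, nc);
  for (int s = 0; s < seg.nrow(); ++s) {
    double x1 = seg(s, 0), y1 = seg(s, 1), x2 = seg(s, 2), y2 = seg(s, 3),
           rad = seg(s, 4);
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy;
    int jlo = std::max(0, (int)std::floor(std::min(x1, x2) - rad) - 1);
    int jhi = std::min(nc - 1, (int)std::ceil(std::max(x1, x2) + rad) + 1);
    int ilo = std::max(0, (int)std::floor(std::min(y1, y2) - rad) - 1);
    int ihi = std::min(nr - 1, (int)std::ceil(std::max(y1, y2) + rad) + 1);
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        double t = len2 > 0 ? ((j - x1) * dx + (i - y1) * dy) / len2 : 0.0;
        t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
        double px = x1 + t * dx, py = y1 + t * dy;
        double d2 = (j - px) * (j - px) + (i - py) * (i - py);
        if (d2 <= rad * rad) out[(size_t)j * nr + i] = intensity;
      }
    }
  }
  return out;
}

// im2col for a (C, H, W) array with square kernel k, stride 1 and symmetric
// zero padding `pad`. Returns (C*k*k) x (outH*outW), column per output
// position (row-major over H then W to match the array layout used in R).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector input, int C, int H, int W, int k,
                         int pad) {
  int oh = H + 2 * pad - k + 1, ow = W + 2 * pad - k + 1;
  NumericMatrix out((R_xlen_t)C * k * k, (R_xlen_t)oh * ow);
  const double *in = REAL(input);
  for (int x = 0; x < ow; ++x) {
    for (int y = 0; y < oh; ++y) {
      R_xlen_t colidx = (R_xlen_t)x * oh + y;
      double *dst = &out[colidx * (R_xlen_t)C * k * k];
      int q = 0;
      for (int kx = 0; kx < k; ++kx) {
        int wx = x + kx - pad;
        for (int ky = 0; ky < k; ++ky) {
          int hy = y + ky - pad;
          bool inside = (wx >= 0 && wx < W && hy >= 0 && hy < H);
          for (int c = 0; c < C; ++c)
            dst[q++] = inside
                           ? in[(size_t)c + (size_t)C * (hy + (size_t)H * wx)]
                           : 0.0;
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling with stride 2 on a (C, H, W) array (H, W even).
// [[Rcpp::export]]
NumericVector cpp_maxpool2(NumericVector input, int C, int H, int W) {
  int oh = H / 2, ow = W / 2;
  NumericVector out((R_xlen_t)C * oh * ow);
  const double *in = REAL(input);
  double *o = REAL(out);
  for (int x = 0; x < ow; ++x)
    for (int y = 0; y < oh; ++y)
      for (int c = 0; c < C; ++c) {
        double m = -1e300;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            double v =
                in[(size_t)c + (size_t)C * ((2 * y + dy) + (size_t)H * (2 * x + dx))];
            if (v > m) m = v;
          }
        o[(size_t)c + (size_t)C * (y + (size_t)oh * x)] = m;
      }
  return out;
}

// Interpolated (type-7) quantile of each row of X.
// [[Rcpp::export]]
NumericVector cpp_row_quantile(NumericMatrix X, double q) {
  int nr = X.nrow(), nc = X.ncol();
  NumericVector out(nr);
  std::vector<double> row(nc);
  double h = (nc - 1) * q;
  int lo = (int)std::floor(h), hi = (int)std::ceil(h);
  double frac = h - lo;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = X(i, j);
    std::nth_element(row.begin(), row.begin() + lo, row.end());
    double vlo = row[lo];
    double vhi = vlo;
    if (hi != lo) {
      vhi = *std::min_element(row.begin() + lo + 1, row.end());
    }
    out[i] = vlo + frac * (vhi - vlo);
  }
  return out;
}
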