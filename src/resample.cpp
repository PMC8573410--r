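// Affine resampling of 3D volumes: cubic B-spline interpolation (with the
// causal/anti-causal recursive prefilter, mirror boundaries) or nearest
// neighbor. The mapping is source = M * dst + o in 0-based voxel coordinates;
// samples falling outside the source grid are set to 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double POLE = -0.26794919243112270647;  // sqrt(3) - 2

// reflect index into [0, n-1] (mirror without repeating the edge sample)
inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = std::abs(i) % p;
  return (i < n) ? i : p - i;
}

void prefilter_line(double* c, int n, int stride) {
  if (n == 1) return;
  const double z = POLE;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal initialization (truncated mirrored sum)
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::abs(z)));
  if (horizon > 2 * n - 2) horizon = 2 * n - 2;
  double sum = c[0];
  double zn = z;
  for (int k = 1; k <= horizon; ++k) {
    sum += zn * c[reflect(k, n) * stride];
    zn *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  // anti-causal initialization
  c[(n - 1) * stride] = (z / (z * z - 1.0)) *
                        (z * c[(n - 2) * stride] + c[(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

void bspline_weights(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

}  // namespace

// [[Rcpp::export(name = ".affine_resample_cpp")]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, NumericVector o,
                                  std::string interpolation) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const bool nearest = (interpolation == "nearest");
  if (!nearest && interpolation != "bspline")
    stop("interpolation must be 'bspline' or 'nearest'");

  std::vector<double> coef;
  if (!nearest) {
    coef.assign(vol.begin(), vol.end());
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        prefilter_line(&coef[(long)nx * y + (long)nx * ny * z], nx, 1);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        prefilter_line(&coef[(long)x + (long)nx * ny * z], ny, nx);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        prefilter_line(&coef[(long)x + (long)nx * y], nz, nx * ny);
  }

  NumericVector out(n);
  double wx[4], wy[4], wz[4];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double sx = M(0, 0) * x + M(0, 1) * y + M(0, 2) * z + o[0];
        const double sy = M(1, 0) * x + M(1, 1) * y + M(1, 2) * z + o[1];
        const double sz = M(2, 0) * x + M(2, 1) * y + M(2, 2) * z + o[2];
        const long oi = (long)x + (long)nx * y + (long)nx * ny * z;
        if (sx < -0.5 || sx > nx - 0.5 || sy < -0.5 || sy > ny - 0.5 ||
            sz < -0.5 || sz > nz - 0.5) {
          out[oi] = 0.0;
          continue;
        }
        if (nearest) {
          const int ix = std::min(nx - 1, std::max(0, (int)std::lround(sx)));
          const int iy = std::min(ny - 1, std::max(0, (int)std::lround(sy)));
          const int iz = std::min(nz - 1, std::max(0, (int)std::lround(sz)));
          out[oi] = vol[(long)ix + (long)nx * iy + (long)nx * ny * iz];
        } else {
          const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
                    fz = (int)std::floor(sz);
          bspline_weights(sx - fx, wx);
          bspline_weights(sy - fy, wy);
          bspline_weights(sz - fz, wz);
          double acc = 0.0;
          for (int kz = 0; kz < 4; ++kz) {
            const int izr = reflect(fz - 1 + kz, nz);
            for (int ky = 0; ky < 4; ++ky) {
              const int iyr = reflect(fy - 1 + ky, ny);
              const double wyz = wy[ky] * wz[kz];
              const long base = (long)nx * iyr + (long)nx * ny * izr;
              double ax = 0.0;
              for (int kx = 0; kx < 4; ++kx)
                ax += wx[kx] * coef[base + reflect(fx - 1 + kx, nx)];
              acc += wyz * ax;
            }
          }
          out[oi] = acc;
        }
      }
  return out;
}
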