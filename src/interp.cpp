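// Separable B-spline interpolation machinery for 3D volumes.
//
// The prefilter converts image samples into B-spline coefficients by
// recursive (IIR) filtering along each axis with mirror-symmetric boundary
// conditions, so that subsequent kernel evaluation interpolates (passes
// through the samples) rather than smoothing. Degrees 0 and 1 need no
// prefilter. Follows the classic recursive-filtering formulation of
// Unser-style spline interpolation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = std::abs(i) % period;
  return (i >= n) ? period - i : i;
}

// ---------------------------------------------------------------------------
// Prefilter
// ---------------------------------------------------------------------------

static int spline_poles(int degree, double *poles) {
  switch (degree) {
  case 0:
  case 1:
    return 0;
  case 2:
    poles[0] = std::sqrt(8.0) - 3.0;
    return 1;
  case 3:
    poles[0] = std::sqrt(3.0) - 2.0;
    return 1;
  case 4:
    poles[0] = std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0;
    poles[1] = std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0;
    return 2;
  default:
    stop("unsupported B-spline degree %d", degree);
  }
  return 0;
}

static double initial_causal(const std::vector<double> &c, double z,
                             double tol) {
  const int n = (int)c.size();
  int horizon = n;
  if (tol > 0.0)
    horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon < n) {
    double zn = z, sum = c[0];
    for (int i = 1; i < horizon; i++) {
      sum += zn * c[i];
      zn *= z;
    }
    return sum;
  }
  // full mirror-periodic sum
  double zn = z;
  double iz = 1.0 / z;
  double z2n = std::pow(z, (double)(n - 1));
  double sum = c[0] + z2n * c[n - 1];
  z2n *= z2n * iz;
  for (int i = 1; i <= n - 2; i++) {
    sum += (zn + z2n) * c[i];
    zn *= z;
    z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static double initial_anticausal(const std::vector<double> &c, double z) {
  const int n = (int)c.size();
  return (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
}

static void filter_line(std::vector<double> &c, const double *poles,
                        int npoles) {
  const int n = (int)c.size();
  if (n == 1) return;
  double lambda = 1.0;
  for (int k = 0; k < npoles; k++) {
    const double z = poles[k];
    lambda *= (1.0 - z) * (1.0 - 1.0 / z);
  }
  for (int i = 0; i < n; i++) c[i] *= lambda;
  for (int k = 0; k < npoles; k++) {
    const double z = poles[k];
    c[0] = initial_causal(c, z, 1e-12);
    for (int i = 1; i < n; i++) c[i] += z * c[i - 1];
    c[n - 1] = initial_anticausal(c, z);
    for (int i = n - 2; i >= 0; i--) c[i] = z * (c[i + 1] - c[i]);
  }
}

// [[Rcpp::export]]
NumericVector spline_filter3_cpp(NumericVector data, IntegerVector dim,
                                 int degree) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(data);
  if (degree <= 1) return out;
  double poles[2];
  const int npoles = spline_poles(degree, poles);

  std::vector<double> line;
  // x lines
  line.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) line[x] = out[base + x];
      filter_line(line, poles, npoles);
      for (int x = 0; x < nx; x++) out[base + x] = line[x];
    }
  // y lines
  line.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) line[y] = out[base + (R_xlen_t)y * nx];
      filter_line(line, poles, npoles);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // z lines
  line.resize(nz);
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) line[z] = out[base + (R_xlen_t)z * slab];
      filter_line(line, poles, npoles);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * slab] = line[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Kernel weights
// ---------------------------------------------------------------------------

// Fills weights for the (degree+1) taps and returns the index of the first
// tap. x is a continuous 0-based voxel coordinate.
static inline int bspline_weights(double x, int degree, double *w) {
  switch (degree) {
  case 0: {
    w[0] = 1.0;
    return (int)std::floor(x + 0.5);
  }
  case 1: {
    const int i = (int)std::floor(x);
    const double t = x - i;
    w[0] = 1.0 - t;
    w[1] = t;
    return i;
  }
  case 2: {
    const int i = (int)std::floor(x + 0.5);
    const double t = x - i;
    w[1] = 0.75 - t * t;
    w[2] = 0.5 * (t - w[1] + 1.0);
    w[0] = 1.0 - w[1] - w[2];
    return i - 1;
  }
  case 3: {
    const int i = (int)std::floor(x);
    const double t = x - i;
    w[3] = (1.0 / 6.0) * t * t * t;
    w[0] = (1.0 / 6.0) + 0.5 * t * (t - 1.0) - w[3];
    w[2] = t + w[0] - 2.0 * w[3];
    w[1] = 1.0 - w[0] - w[2] - w[3];
    return i - 1;
  }
  case 4: {
    const int i = (int)std::floor(x + 0.5);
    const double t = x - i;
    const double t2 = t * t;
    double u = 0.5 - t;
    u *= u;
    w[0] = (1.0 / 24.0) * u * u;
    const double tt = (1.0 / 6.0) * t2;
    const double t0 = t * (tt - 11.0 / 24.0);
    const double t1 = 19.0 / 96.0 + t2 * (0.25 - tt);
    w[1] = t1 + t0;
    w[3] = t1 - t0;
    w[4] = w[0] + t0 + 0.5 * t;
    w[2] = 1.0 - w[0] - w[1] - w[3] - w[4];
    return i - 2;
  }
  default:
    stop("unsupported B-spline degree %d", degree);
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Evaluation at arbitrary continuous voxel coordinates
// ---------------------------------------------------------------------------

// coef: prefiltered coefficients (raw samples for degree <= 1)
// coords: N x 3 matrix of 0-based continuous voxel coordinates
// Points outside the convex hull of voxel centres [0, dim-1] evaluate to
// `background` (constant padding); taps spilling past the edge for interior
// points use mirror indices, consistent with the prefilter.
// [[Rcpp::export]]
NumericVector bspline_eval3_cpp(NumericVector coef, IntegerVector dim,
                                NumericMatrix coords, int degree,
                                double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const int nt = degree + 1;
  double wx[5], wy[5], wz[5];
  int ix[5], iy[5], iz[5];
  const double ex = (double)(nx - 1), ey = (double)(ny - 1),
               ez = (double)(nz - 1);
  const double eps = 1e-6;  // tolerate rounding at the domain boundary

  for (R_xlen_t p = 0; p < n; p++) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!(x >= -eps && x <= ex + eps && y >= -eps && y <= ey + eps &&
          z >= -eps && z <= ez + eps) ||
        ISNAN(x) || ISNAN(y) || ISNAN(z)) {
      out[p] = background;
      continue;
    }
    x = std::min(std::max(x, 0.0), ex);
    y = std::min(std::max(y, 0.0), ey);
    z = std::min(std::max(z, 0.0), ez);
    const int fx = bspline_weights(x, degree, wx);
    const int fy = bspline_weights(y, degree, wy);
    const int fz = bspline_weights(z, degree, wz);
    for (int k = 0; k < nt; k++) {
      ix[k] = mirror_index(fx + k, nx);
      iy[k] = mirror_index(fy + k, ny);
      iz[k] = mirror_index(fz + k, nz);
    }
    double acc = 0.0;
    for (int c = 0; c < nt; c++) {
      const R_xlen_t zoff = (R_xlen_t)iz[c] * nx * ny;
      double accy = 0.0;
      for (int b = 0; b < nt; b++) {
        const R_xlen_t yoff = zoff + (R_xlen_t)iy[b] * nx;
        double accx = 0.0;
        for (int a = 0; a < nt; a++) accx += wx[a] * coef[yoff + ix[a]];
        accy += wy[b] * accx;
      }
      acc += wz[c] * accy;
    }
    out[p] = acc;
  }
  return out;
}

// Adjoint of evaluation: scatters each value into the coefficient grid with
// the same tensor-product weights. Used for gradient splatting in free-form
// deformation registration. Out-of-range taps are dropped.
// [[Rcpp::export]]
NumericVector bspline_splat3_cpp(NumericVector values, NumericMatrix coords,
                                 IntegerVector dim, int degree) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int nt = degree + 1;
  double wx[5], wy[5], wz[5];
  const R_xlen_t n = coords.nrow();
  for (R_xlen_t p = 0; p < n; p++) {
    const double v = values[p];
    if (v == 0.0) continue;
    const int fx = bspline_weights(coords(p, 0), degree, wx);
    const int fy = bspline_weights(coords(p, 1), degree, wy);
    const int fz = bspline_weights(coords(p, 2), degree, wz);
    for (int c = 0; c < nt; c++) {
      const int z = fz + c;
      if (z < 0 || z >= nz) continue;
      for (int b = 0; b < nt; b++) {
        const int y = fy + b;
        if (y < 0 || y >= ny) continue;
        const double wzy = wz[c] * wy[b] * v;
        const R_xlen_t off = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int a = 0; a < nt; a++) {
          const int x = fx + a;
          if (x < 0 || x >= nx) continue;
          out[off + x] += wx[a] * wzy;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (reflect boundary, kernel truncated at 3 sigma)
// ---------------------------------------------------------------------------

static void gauss_line(std::vector<double> &line, const std::vector<double> &k) {
  const int n = (int)line.size();
  const int r = ((int)k.size() - 1) / 2;
  std::vector<double> src(line);
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int j = -r; j <= r; j++)
      acc += k[j + r] * src[mirror_index(i + j, n)];
    line[i] = acc;
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector gauss_smooth3_cpp(NumericVector data, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(data);
  std::vector<double> line;
  if (sigma[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma[0]);
    line.resize(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; x++) line[x] = out[base + x];
        gauss_line(line, k);
        for (int x = 0; x < nx; x++) out[base + x] = line[x];
      }
  }
  if (sigma[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma[1]);
    line.resize(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) line[y] = out[base + (R_xlen_t)y * nx];
        gauss_line(line, k);
        for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = line[y];
      }
  }
  if (sigma[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma[2]);
    line.resize(nz);
    const R_xlen_t slab = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        const R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) line[z] = out[base + z * slab];
        gauss_line(line, k);
        for (int z = 0; z < nz; z++) out[base + z * slab] = line[z];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 6-connected components (stack-based flood fill), labels in scan order
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label_components6_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t i = stack.back();
      stack.pop_back();
      const int x = (int)(i % nx);
      const int y = (int)((i / nx) % ny);
      const int z = (int)(i / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        const int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        const R_xlen_t j = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
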