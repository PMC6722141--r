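#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All kernels operate in voxel-index space (0-based internally); displacement
// vectors are in voxel units along the array axes. Out-of-domain samples take
// the background value 0 for images and fields alike.

static inline double sample_trilinear(const double *a, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x < -1.0 || y < -1.0 || z < -1.0 || x > nx || y > ny || z > nz)
    return 0.0;
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
        out += wx * wy * wz * a[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return out;
}

// Edge-clamped trilinear sampling, used for vector fields: displacement
// fields are extended by their boundary values rather than by zero, so that
// flows leaving the grid stay consistent between integration schemes.
static inline double sample_trilinear_clamp(const double *a, int nx, int ny,
                                            int nz, double x, double y,
                                            double z) {
  if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        out += w * a[(x0 + dx) +
                     (size_t)nx * ((y0 + dy) + (size_t)ny * (z0 + dz))];
      }
  return out;
}

static void get_dim3(const NumericVector &v, int &nx, int &ny, int &nz) {
  IntegerVector d = v.attr("dim");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// out(x) = img(x + field(x)), trilinear, zero background.
// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector img, NumericVector field) {
  int nx, ny, nz;
  get_dim3(img, nx, ny, nz);
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double *a = img.begin();
  const double *ux = field.begin();
  const double *uy = ux + n, *uz = uy + n;
  double *o = out.begin();
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i)
        o[i] = sample_trilinear(a, nx, ny, nz,
                                x + ux[i], y + uy[i], z + uz[i]);
  return out;
}

// Nearest-neighbour variant for label maps.
// [[Rcpp::export]]
NumericVector cpp_warp_nearest(NumericVector img, NumericVector field) {
  int nx, ny, nz;
  get_dim3(img, nx, ny, nz);
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double *a = img.begin();
  const double *ux = field.begin();
  const double *uy = ux + n, *uz = uy + n;
  double *o = out.begin();
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        long xx = std::lround(x + ux[i]);
        long yy = std::lround(y + uy[i]);
        long zz = std::lround(z + uz[i]);
        o[i] = (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                 ? 0.0
                 : a[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
  return out;
}

// result(x) = outer(x) + inner(x + outer(x)); warping by the result equals
// warping by `inner` first, then by `outer` (pull-back convention).
// [[Rcpp::export]]
NumericVector cpp_compose_fields(NumericVector outer, NumericVector inner) {
  IntegerVector d = outer.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(outer.size());
  out.attr("dim") = outer.attr("dim");
  const double *ox = outer.begin(), *oy = ox + n, *oz = oy + n;
  const double *ix = inner.begin(), *iy = ix + n, *iz = iy + n;
  double *rx = out.begin(), *ry = rx + n, *rz = ry + n;
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double px = x + ox[i], py = y + oy[i], pz = z + oz[i];
        if (px < 0) px = 0; else if (px > nx - 1) px = nx - 1;
        if (py < 0) py = 0; else if (py > ny - 1) py = ny - 1;
        if (pz < 0) pz = 0; else if (pz > nz - 1) pz = nz - 1;
        int x0 = (int)px, y0 = (int)py, z0 = (int)pz;
        if (x0 > nx - 2) x0 = nx - 2;
        if (y0 > ny - 2) y0 = ny - 2;
        if (z0 > nz - 2) z0 = nz - 2;
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        double w000 = (1 - fx) * (1 - fy) * (1 - fz);
        double w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz);
        double w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz;
        double w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz;
        double w111 = fx * fy * fz;
        size_t b = x0 + (size_t)nx * (y0 + (size_t)ny * z0);
        size_t sy = nx, sz = (size_t)nx * ny;
#define HG_SAMP(arr) (w000 * arr[b] + w100 * arr[b + 1] + \
                      w010 * arr[b + sy] + w110 * arr[b + 1 + sy] + \
                      w001 * arr[b + sz] + w101 * arr[b + 1 + sz] + \
                      w011 * arr[b + sy + sz] + w111 * arr[b + 1 + sy + sz])
        rx[i] = ox[i] + HG_SAMP(ix);
        ry[i] = oy[i] + HG_SAMP(iy);
        rz[i] = oz[i] + HG_SAMP(iz);
#undef HG_SAMP
      }
  return out;
}

// Separable Gaussian smoothing along the three spatial axes, applied to each
// trailing component independently; clamped (replicate) boundaries so that a
// constant field stays constant. Kernel truncated at 3 sigma. Lines along
// the smoothing axis are convolved with a branch-free interior loop.
static void smooth_line(const double *in, double *out, int len, size_t stride,
                        const std::vector<double> &k) {
  int r = (int)k.size() / 2;
  for (int p = 0; p < len; ++p) {
    double s = 0.0;
    if (p >= r && p < len - r) {
      const double *q = in + (size_t)(p - r) * stride;
      for (int t = 0; t < 2 * r + 1; ++t, q += stride) s += k[t] * *q;
    } else {
      for (int t = -r; t <= r; ++t) {
        int pp = p + t;
        if (pp < 0) pp = 0;
        if (pp >= len) pp = len - 1;
        s += k[t + r] * in[(size_t)pp * stride];
      }
    }
    out[(size_t)p * stride] = s;
  }
}

static void smooth_axis(double *a, double *tmp, int nx, int ny, int nz,
                        int ncomp, int axis, const std::vector<double> &k) {
  size_t n = (size_t)nx * ny * nz;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx
                                             : (size_t)nx * ny);
  for (int c = 0; c < ncomp; ++c) {
    double *ac = a + c * n;
    if (axis == 0) {
      for (size_t line = 0; line < (size_t)ny * nz; ++line)
        smooth_line(ac + line * nx, tmp + line * nx, len, 1, k);
    } else if (axis == 1) {
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
          size_t off = x + (size_t)nx * ny * z;
          smooth_line(ac + off, tmp + off, len, stride, k);
        }
    } else {
      for (size_t off = 0; off < (size_t)nx * ny; ++off)
        smooth_line(ac + off, tmp + off, len, stride, k);
    }
    std::copy(tmp, tmp + n, ac);
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, double sigma) {
  if (sigma <= 0) return clone(arr);
  IntegerVector d = arr.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ncomp = 1;
  for (int i = 3; i < d.size(); ++i) ncomp *= d[i];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double sum = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    sum += k[t + r];
  }
  for (double &w : k) w /= sum;
  NumericVector out = clone(arr);
  std::vector<double> tmp((size_t)nx * ny * nz);
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(out.begin(), tmp.data(), nx, ny, nz, ncomp, axis, k);
  out.attr("dim") = arr.attr("dim");
  return out;
}

// Central-difference gradient (one-sided at borders); returns a 4D array
// [nx,ny,nz,3] in intensity units per voxel.
// [[Rcpp::export]]
NumericVector cpp_gradient(NumericVector img) {
  int nx, ny, nz;
  get_dim3(img, nx, ny, nz);
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double *a = img.begin();
  double *gx = out.begin(), *gy = gx + n, *gz = gy + n;
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        int xm = x > 0 ? x - 1 : 0, xp = x < nx - 1 ? x + 1 : nx - 1;
        int ym = y > 0 ? y - 1 : 0, yp = y < ny - 1 ? y + 1 : ny - 1;
        int zm = z > 0 ? z - 1 : 0, zp = z < nz - 1 ? z + 1 : nz - 1;
        gx[i] = (a[xp + (size_t)nx * (y + (size_t)ny * z)] -
                 a[xm + (size_t)nx * (y + (size_t)ny * z)]) / (double)(xp - xm);
        gy[i] = (a[x + (size_t)nx * (yp + (size_t)ny * z)] -
                 a[x + (size_t)nx * (ym + (size_t)ny * z)]) / (double)(yp - ym);
        gz[i] = (a[x + (size_t)nx * (y + (size_t)ny * zp)] -
                 a[x + (size_t)nx * (y + (size_t)ny * zm)]) / (double)(zp - zm);
      }
  return out;
}

// Resample a 3D scalar array to new dimensions with align-corners trilinear
// interpolation (endpoints map to endpoints).
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector img, IntegerVector newdim) {
  int nx, ny, nz;
  get_dim3(img, nx, ny, nz);
  int mx = newdim[0], my = newdim[1], mz = newdim[2];
  NumericVector out((size_t)mx * my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  const double *a = img.begin();
  double *o = out.begin();
  double sx = mx > 1 ? (double)(nx - 1) / (mx - 1) : 0.0;
  double sy = my > 1 ? (double)(ny - 1) / (my - 1) : 0.0;
  double sz = mz > 1 ? (double)(nz - 1) / (mz - 1) : 0.0;
  size_t i = 0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x, ++i)
        o[i] = sample_trilinear(a, nx, ny, nz, x * sx, y * sy, z * sz);
  return out;
}

// Symmetric demons update force: diff * J / (|J|^2 + diff^2 / cap^2), where
// J is the mean of the fixed and warped-moving gradients, with the per-voxel
// step clamped to `cap` voxels. Returns a 4D [nx,ny,nz,3] update field.
// [[Rcpp::export]]
NumericVector cpp_demons_force(NumericVector fixedimg, NumericVector warped,
                               NumericVector gfixed, NumericVector gwarp,
                               double cap) {
  int nx, ny, nz;
  get_dim3(fixedimg, nx, ny, nz);
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double *f = fixedimg.begin(), *m = warped.begin();
  const double *fx = gfixed.begin(), *fy = fx + n, *fz = fy + n;
  const double *mx = gwarp.begin(), *my = mx + n, *mz = my + n;
  double *ux = out.begin(), *uy = ux + n, *uz = uy + n;
  double cap2 = cap * cap;
  for (size_t i = 0; i < n; ++i) {
    double diff = f[i] - m[i];
    double jx = 0.5 * (fx[i] + mx[i]);
    double jy = 0.5 * (fy[i] + my[i]);
    double jz = 0.5 * (fz[i] + mz[i]);
    double j2 = jx * jx + jy * jy + jz * jz;
    double denom = j2 + diff * diff / cap2;
    if (denom < 1e-12) { ux[i] = uy[i] = uz[i] = 0.0; continue; }
    double s = diff / denom;
    double vx = s * jx, vy = s * jy, vz = s * jz;
    double mag = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (mag > cap) { vx *= cap / mag; vy *= cap / mag; vz *= cap / mag; }
    ux[i] = vx; uy[i] = vy; uz[i] = vz;
  }
  return out;
}

// Maximum per-voxel Euclidean vector magnitude of a [nx,ny,nz,3] field.
// [[Rcpp::export]]
double cpp_max_magnitude(NumericVector field) {
  size_t n = field.size() / 3;
  const double *x = field.begin(), *y = x + n, *z = y + n;
  double best = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double m = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
    if (m != m) return R_NaN;   // propagate NaN so callers can reject it
    if (m > best) best = m;
  }
  return std::sqrt(best);
}
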