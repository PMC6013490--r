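// 3D binary morphology, connected components, region growing, separable
// Gaussian smoothing and rigid trilinear resampling for volumes stored as
// column-major R arrays with dims (nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Chebyshev-ball (iterated 26-neighbourhood) dilation/erosion via separable
// running box max/min along each axis.
static void box_filter_axis(std::vector<unsigned char> &v, int nx, int ny,
                            int nz, int r, int axis, bool take_max) {
  std::vector<unsigned char> out(v.size());
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int a = 0; a < (axis == 0 ? ny : nx); ++a) {
    for (int b = 0; b < (axis == 2 ? ny : nz); ++b) {
      for (int i = 0; i < len; ++i) {
        unsigned char acc = take_max ? 0 : 1;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          int x, y, z;
          if (axis == 0) { x = j; y = a; z = b; }
          else if (axis == 1) { x = a; y = j; z = b; }
          else { x = a; y = b; z = j; }
          unsigned char val = v[idx3(x, y, z, nx, ny)];
          if (take_max) { if (val) { acc = 1; break; } }
          else { if (!val) { acc = 0; break; } }
        }
        int x, y, z;
        if (axis == 0) { x = i; y = a; z = b; }
        else if (axis == 1) { x = a; y = i; z = b; }
        else { x = a; y = b; z = i; }
        out[idx3(x, y, z, nx, ny)] = acc;
      }
    }
  }
  v.swap(out);
}

static std::vector<unsigned char> as_uchar(const LogicalVector &mask) {
  std::vector<unsigned char> v(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) v[i] = (mask[i] == TRUE) ? 1 : 0;
  return v;
}

static LogicalVector as_logical(const std::vector<unsigned char> &v,
                                const IntegerVector &dim) {
  LogicalVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, int radius) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<unsigned char> v = as_uchar(mask);
  for (int axis = 0; axis < 3; ++axis)
    box_filter_axis(v, nx, ny, nz, radius, axis, true);
  return as_logical(v, dim);
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, int radius) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<unsigned char> v = as_uchar(mask);
  for (int axis = 0; axis < 3; ++axis)
    box_filter_axis(v, nx, ny, nz, radius, axis, false);
  return as_logical(v, dim);
}

// 26-connected component labelling (BFS); labels 1..n, 0 outside mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny), rem = cur % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int q = idx3(xx, yy, zz, nx, ny);
            if (mask[q] == TRUE && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}

// Seeded region growing: expand from seed voxels through candidate voxels
// (26-connectivity) whose intensity lies in [lo, hi].
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, LogicalVector candidate,
                              LogicalVector seeds, double lo, double hi) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = vol.size();
  LogicalVector out(n, false);
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] == TRUE && candidate[i] == TRUE) {
      out[i] = true;
      stack.push_back((int)i);
    }
  }
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int z = cur / (nx * ny), rem = cur % (nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int q = idx3(xx, yy, zz, nx, ny);
          if (out[q] == TRUE || candidate[q] != TRUE) continue;
          double v = vol[q];
          if (v >= lo && v <= hi) {
            out[q] = true;
            stack.push_back(q);
          }
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and renormalized
// at the volume borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, double sigma) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis];
    for (int z = 0; z < (axis == 2 ? ny : nz); ++z)
      for (int y = 0; y < (axis == 0 ? ny : nx); ++y)
        for (int i = 0; i < len; ++i) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
          for (int j = lo; j <= hi; ++j) {
            int x0, y0, z0;
            if (axis == 0) { x0 = j; y0 = y; z0 = z; }
            else if (axis == 1) { x0 = y; y0 = j; z0 = z; }
            else { x0 = y; y0 = z; z0 = j; }
            double w = k[j - i + r];
            acc += w * a[idx3(x0, y0, z0, nx, ny)];
            wsum += w;
          }
          int x0, y0, z0;
          if (axis == 0) { x0 = i; y0 = y; z0 = z; }
          else if (axis == 1) { x0 = y; y0 = i; z0 = z; }
          else { x0 = y; y0 = z; z0 = i; }
          b[idx3(x0, y0, z0, nx, ny)] = acc / wsum;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Resample `vol` onto a grid of the same dims under an affine map taking
// output voxel coordinates (0-based) to input voxel coordinates:
// p_in = A %*% p_out + t, with A = m[1:3,1:3], t = m[1:3,4].
// Trilinear interpolation, `fill` outside the input grid.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, NumericMatrix m,
                                  double fill) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double sx = m(0, 0) * x + m(0, 1) * y + m(0, 2) * z + m(0, 3);
        double sy = m(1, 0) * x + m(1, 1) * y + m(1, 2) * z + m(1, 3);
        double sz = m(2, 0) * x + m(2, 1) * y + m(2, 2) * z + m(2, 3);
        double val = fill;
        if (sx >= 0 && sy >= 0 && sz >= 0 && sx <= nx - 1 && sy <= ny - 1 &&
            sz <= nz - 1) {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double c000 = vol[idx3(x0, y0, z0, nx, ny)];
          double c100 = vol[idx3(x1, y0, z0, nx, ny)];
          double c010 = vol[idx3(x0, y1, z0, nx, ny)];
          double c110 = vol[idx3(x1, y1, z0, nx, ny)];
          double c001 = vol[idx3(x0, y0, z1, nx, ny)];
          double c101 = vol[idx3(x1, y0, z1, nx, ny)];
          double c011 = vol[idx3(x0, y1, z1, nx, ny)];
          double c111 = vol[idx3(x1, y1, z1, nx, ny)];
          val = c000 * (1 - fx) * (1 - fy) * (1 - fz) +
                c100 * fx * (1 - fy) * (1 - fz) +
                c010 * (1 - fx) * fy * (1 - fz) + c110 * fx * fy * (1 - fz) +
                c001 * (1 - fx) * (1 - fy) * fz + c101 * fx * (1 - fy) * fz +
                c011 * (1 - fx) * fy * fz + c111 * fx * fy * fz;
        }
        out[idx3(x, y, z, nx, ny)] = val;
      }
  out.attr("dim") = dim;
  return out;
}

// Euclidean-ball dilation/erosion (structuring element: voxels with
// center distance <= radius).
static LogicalVector ball_morph(LogicalVector mask, double radius,
                                bool dilate) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          offs.push_back({dx, dy, dz});
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool acc = !dilate;
        for (size_t i = 0; i < offs.size(); ++i) {
          int xx = x + offs[i][0], yy = y + offs[i][1], zz = z + offs[i][2];
          bool v;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            v = false;  // outside the grid counts as background
          else
            v = mask[idx3(xx, yy, zz, nx, ny)] == TRUE;
          if (dilate && v) { acc = true; break; }
          if (!dilate && !v) { acc = false; break; }
        }
        out[idx3(x, y, z, nx, ny)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_ball(LogicalVector mask, double radius) {
  return ball_morph(mask, radius, true);
}

// [[Rcpp::export]]
LogicalVector cpp_erode_ball(LogicalVector mask, double radius) {
  return ball_morph(mask, radius, false);
}
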