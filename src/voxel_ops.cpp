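#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Trilinear interpolation helpers operate in 0-based voxel coordinates.
// Out-of-field samples take the supplied background value.

static inline double clamp_coord(double x, int n) {
  // tolerate floating-point noise at the field boundary
  const double eps = 1e-6;
  if (x > -eps && x < 0) return 0.0;
  if (x > n - 1 && x < n - 1 + eps) return n - 1;
  return x;
}

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, double bg,
                                bool *oob) {
  x = clamp_coord(x, nx);
  y = clamp_coord(y, ny);
  z = clamp_coord(z, nz);
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    if (oob) *oob = true;
    return bg;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  // snap near-integer weights so exact grid hits reduce to single voxels
  const double eps = 1e-6;
  if (fx < eps) fx = 0; else if (fx > 1 - eps) fx = 1;
  if (fy < eps) fy = 0; else if (fy > 1 - eps) fy = 1;
  if (fz < eps) fz = 0; else if (fz > 1 - eps) fz = 1;
  double acc = 0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        if (w == 0) continue;
        acc += w * v[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
      }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = tri_sample(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2),
                        background, nullptr);
  return out;
}

// A maps 0-based output voxel index -> 0-based input voxel coordinate (3x4).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector dim_out, NumericMatrix A,
                                  double background, bool nearest) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = vol.begin();
  double *o = out.begin();
  size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        if (nearest) {
          int ii = (int)std::lround(x), jj = (int)std::lround(y),
              kk = (int)std::lround(z);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            o[idx] = background;
          else
            o[idx] = v[ii + (size_t)nx * (jj + (size_t)ny * kk)];
        } else {
          o[idx] = tri_sample(v, nx, ny, nz, x, y, z, background, nullptr);
        }
      }
  out.attr("dim") = dim_out;
  return out;
}

// Separable Gaussian blur, sigma per axis in voxels; truncated at 3 sigma.
// Edge handling: kernel renormalized over the in-field support.
static void blur_axis(std::vector<double> &buf, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma;
  for (int i = -radius; i <= radius; ++i) k[i + radius] = std::exp(-i * i / s2);
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  size_t total = (size_t)nx * ny * nz;
  tmp.assign(total, 0.0);
  int na = n[axis];
  size_t sa = stride[axis];
  for (size_t base = 0; base < total; ++base) {
    // compute coordinate along axis
    size_t rem = base;
    int coord[3];
    coord[2] = (int)(rem / stride[2]); rem %= stride[2];
    coord[1] = (int)(rem / stride[1]); rem %= stride[1];
    coord[0] = (int)rem;
    int c = coord[axis];
    double acc = 0, wsum = 0;
    int lo = std::max(0, c - radius), hi = std::min(na - 1, c + radius);
    for (int p = lo; p <= hi; ++p) {
      double w = k[p - c + radius];
      acc += w * buf[base + ((size_t)p - c) * sa];
      wsum += w;
    }
    tmp[base] = acc / wsum;
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(vol.begin(), vol.end()), tmp;
  for (int a = 0; a < 3; ++a) blur_axis(buf, tmp, nx, ny, nz, a, sigma_vox[a]);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labeling of a logical volume (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label_components26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t total = (size_t)nx * ny * nz;
  IntegerVector labels(total, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < total; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[q] && !labels[q]) {
              labels[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Masked mutual information with partial-volume (linear) weighting over a
// pre-binned moving volume. mov_bin holds, per moving voxel, its histogram
// bin or -1 for invalid (metal-excluded or masked-out) voxels; samples
// whose 8-voxel support touches an invalid or out-of-field voxel are
// dropped entirely. Returns MI in nats plus the retained sample count.
// [[Rcpp::export]]
List cpp_mi_binned(IntegerVector fixed_bin, NumericMatrix pts, NumericMatrix M,
                   IntegerVector mov_bin, IntegerVector dim,
                   int n_bins_f, int n_bins_m) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *mb = mov_bin.begin();
  std::vector<double> joint((size_t)n_bins_f * n_bins_m, 0.0);
  int n = pts.nrow();
  double used = 0;
  const double eps = 1e-6;
  for (int s = 0; s < n; ++s) {
    double px = pts(s, 0), py = pts(s, 1), pz = pts(s, 2);
    double x = clamp_coord(M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + M(0, 3), nx);
    double y = clamp_coord(M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + M(1, 3), ny);
    double z = clamp_coord(M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + M(2, 3), nz);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (fx < eps) fx = 0; else if (fx > 1 - eps) fx = 1;
    if (fy < eps) fy = 0; else if (fy > 1 - eps) fy = 1;
    if (fz < eps) fz = 0; else if (fz > 1 - eps) fz = 1;
    double w[8];
    int bins[8];
    bool bad = false;
    int m = 0;
    for (int dk = 0; dk < 2 && !bad; ++dk)
      for (int dj = 0; dj < 2 && !bad; ++dj)
        for (int di = 0; di < 2 && !bad; ++di) {
          double ww =
              (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (ww == 0) continue;
          int b = mb[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
          if (b < 0) { bad = true; break; }
          w[m] = ww;
          bins[m] = b;
          ++m;
        }
    if (bad || m == 0) continue;
    int fb = fixed_bin[s];
    for (int t = 0; t < m; ++t)
      joint[fb + (size_t)n_bins_f * bins[t]] += w[t];
    used += 1;
  }
  double total = 0;
  for (double c : joint) total += c;
  if (total <= 0)
    return List::create(_["mi"] = NA_REAL, _["n_used"] = 0.0);
  std::vector<double> pf(n_bins_f, 0.0), pm(n_bins_m, 0.0);
  for (int mbn = 0; mbn < n_bins_m; ++mbn)
    for (int fb = 0; fb < n_bins_f; ++fb) {
      double p = joint[fb + (size_t)n_bins_f * mbn] / total;
      pf[fb] += p;
      pm[mbn] += p;
    }
  double hf = 0, hm = 0, hj = 0;
  for (double p : pf) if (p > 0) hf -= p * std::log(p);
  for (double p : pm) if (p > 0) hm -= p * std::log(p);
  for (double p : joint)
    if (p > 0) { double q = p / total; hj -= q * std::log(q); }
  return List::create(_["mi"] = hf + hm - hj, _["n_used"] = used,
                      _["h_fixed"] = hf, _["h_moving"] = hm,
                      _["h_joint"] = hj);
}

// Masked mutual information with partial-volume (linear) weighting.
// fixed_bin: 0-based bin per sample; pts: sample points in fixed WORLD mm;
// M: 3x4 composed map fixed-world -> moving 0-based voxel coords;
// moving: moving volume; excl: optional integer volume in moving space
// (nonzero = excluded, checked at the nearest voxel); samples whose 8-voxel
// support touches an out-of-field, excluded or supra-threshold voxel are
// dropped entirely. Returns MI in nats plus the retained sample count.
// [[Rcpp::export]]
List cpp_mi_masked(IntegerVector fixed_bin, NumericMatrix pts, NumericMatrix M,
                   NumericVector moving, IntegerVector dim, Nullable<IntegerVector> excl,
                   int n_bins_f, int n_bins_m, double mov_lo, double mov_hi,
                   double threshold) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = moving.begin();
  const int *ex = nullptr;
  if (excl.isNotNull()) ex = IntegerVector(excl).begin();
  std::vector<double> joint((size_t)n_bins_f * n_bins_m, 0.0);
  double binw = (mov_hi - mov_lo) / n_bins_m;
  if (binw <= 0) binw = 1.0;
  int n = pts.nrow();
  double used = 0;
  const double eps = 1e-6;
  for (int s = 0; s < n; ++s) {
    double px = pts(s, 0), py = pts(s, 1), pz = pts(s, 2);
    double x = clamp_coord(M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + M(0, 3), nx);
    double y = clamp_coord(M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + M(1, 3), ny);
    double z = clamp_coord(M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + M(2, 3), nz);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      continue;
    if (ex) {
      int ii = (int)std::lround(x), jj = (int)std::lround(y),
          kk = (int)std::lround(z);
      if (ex[ii + (size_t)nx * (jj + (size_t)ny * kk)]) continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (fx < eps) fx = 0; else if (fx > 1 - eps) fx = 1;
    if (fy < eps) fy = 0; else if (fy > 1 - eps) fy = 1;
    if (fz < eps) fz = 0; else if (fz > 1 - eps) fz = 1;
    double w[8], val[8];
    bool bad = false;
    int m = 0;
    for (int dk = 0; dk < 2 && !bad; ++dk)
      for (int dj = 0; dj < 2 && !bad; ++dj)
        for (int di = 0; di < 2 && !bad; ++di) {
          double ww =
              (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (ww == 0) continue;
          double vv =
              v[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
          if (vv >= threshold) { bad = true; break; }
          w[m] = ww;
          val[m] = vv;
          ++m;
        }
    if (bad || m == 0) continue;
    int fb = fixed_bin[s];
    for (int t = 0; t < m; ++t) {
      int mb = (int)std::floor((val[t] - mov_lo) / binw);
      if (mb < 0) mb = 0;
      if (mb >= n_bins_m) mb = n_bins_m - 1;
      joint[fb + (size_t)n_bins_f * mb] += w[t];
    }
    used += 1;
  }
  double total = 0;
  for (double c : joint) total += c;
  if (total <= 0)
    return List::create(_["mi"] = NA_REAL, _["n_used"] = 0.0);
  std::vector<double> pf(n_bins_f, 0.0), pm(n_bins_m, 0.0);
  for (int mb = 0; mb < n_bins_m; ++mb)
    for (int fb = 0; fb < n_bins_f; ++fb) {
      double p = joint[fb + (size_t)n_bins_f * mb] / total;
      pf[fb] += p;
      pm[mb] += p;
    }
  double hf = 0, hm = 0, hj = 0;
  for (double p : pf) if (p > 0) hf -= p * std::log(p);
  for (double p : pm) if (p > 0) hm -= p * std::log(p);
  for (double p : joint)
    if (p > 0) { double q = p / total; hj -= q * std::log(q); }
  double mi = hf + hm - hj;
  return List::create(_["mi"] = mi, _["n_used"] = used,
                      _["h_fixed"] = hf, _["h_moving"] = hm, _["h_joint"] = hj);
}
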