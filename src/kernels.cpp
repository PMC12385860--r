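// Spatial kernels: exact anisotropic EDT, connected components,
// nearest-pair search, affine pull-back resampling, segment rasterization.
// Index convention throughout: R array dim = (nx, ny, nz), x fastest;
// linear index (0-based) = i + nx * (j + ny * k); voxel centre of (i,j,k)
// sits at origin + (i*sx, j*sy, k*sz) in mm.
#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EDT_INF = 1e30;

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// with grid step w (mm) so the result is exact on anisotropic lattices.
static void edt1d(const double* f, double* d, int n, double w,
                  int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// foreground voxel centre. Exact for axis-aligned anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? 0.0 : EDT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      edt1d(f.data(), out.data(), nx, spacing[0], v.data(), z.data());
      for (int i = 0; i < nx; ++i) d[base + i] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)nx * j];
      edt1d(f.data(), out.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = out[j];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + sz * k];
      edt1d(f.data(), out.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; ++k) d[base + sz * k] = out[k];
    }
  return d;
}

// Connected-component labelling by breadth-first search; labels are
// assigned 1..K in raster-scan order of each component's first voxel,
// so the labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> off_i, off_j, off_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off_i.push_back(di); off_j.push_back(dj); off_k.push_back(dk);
      }
  const int noff = (int)off_i.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int t = 0; t < noff; ++t) {
        int ii = i + off_i[t], jj = j + off_j[t], kk = k + off_k[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (fg[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Closest pair of points between two mm-coordinate sets (rows = points).
// Exhaustive search; ties broken by lowest (iA, iB) so the result is
// deterministic. Returns 1-based indices.
// [[Rcpp::export]]
List cpp_nearest_pair(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  int bi = -1, bj = -1;
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1,
                      _["distance"] = std::sqrt(best));
}

// Pull-back resampling: for each output voxel centre p (defined by the
// output grid), evaluate the source volume at q = A p + t, by trilinear
// (linear = true) or nearest-neighbour interpolation. Out-of-field
// voxels receive `fill` and are flagged in `inside`.
// [[Rcpp::export]]
List cpp_resample(NumericVector src, IntegerVector sdim,
                  NumericVector sspacing, NumericVector sorigin,
                  IntegerVector odim, NumericVector ospacing,
                  NumericVector oorigin, NumericMatrix A,
                  NumericVector tr, bool linear, double fill) {
  const int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const int onx = odim[0], ony = odim[1], onz = odim[2];
  const R_xlen_t nout = (R_xlen_t)onx * ony * onz;
  NumericVector out(nout);
  LogicalVector inside(nout);
  const R_xlen_t sxy = (R_xlen_t)snx * sny;

  R_xlen_t idx = 0;
  for (int k = 0; k < onz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < ony; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < onx; ++i, ++idx) {
        double px = oorigin[0] + i * ospacing[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + tr[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + tr[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + tr[2];
        double u = (qx - sorigin[0]) / sspacing[0];
        double v = (qy - sorigin[1]) / sspacing[1];
        double w = (qz - sorigin[2]) / sspacing[2];
        if (linear) {
          if (u < 0 || v < 0 || w < 0 ||
              u > snx - 1 || v > sny - 1 || w > snz - 1) {
            out[idx] = fill;
            inside[idx] = false;
            continue;
          }
          int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
          if (i0 > snx - 2) i0 = snx - 2;
          if (j0 > sny - 2) j0 = sny - 2;
          if (k0 > snz - 2) k0 = snz - 2;
          if (i0 < 0) i0 = 0;
          if (j0 < 0) j0 = 0;
          if (k0 < 0) k0 = 0;
          double fu = u - i0, fv = v - j0, fw = w - k0;
          R_xlen_t b000 = i0 + (R_xlen_t)snx * (j0 + (R_xlen_t)sny * k0);
          double c00 = src[b000] * (1 - fu) + src[b000 + 1] * fu;
          double c10 = src[b000 + snx] * (1 - fu) + src[b000 + snx + 1] * fu;
          double c01 = src[b000 + sxy] * (1 - fu) + src[b000 + sxy + 1] * fu;
          double c11 = src[b000 + sxy + snx] * (1 - fu) +
                       src[b000 + sxy + snx + 1] * fu;
          double c0 = c00 * (1 - fv) + c10 * fv;
          double c1 = c01 * (1 - fv) + c11 * fv;
          out[idx] = c0 * (1 - fw) + c1 * fw;
          inside[idx] = true;
        } else {
          int in = (int)std::lround(u), jn = (int)std::lround(v),
              kn = (int)std::lround(w);
          if (in < 0 || jn < 0 || kn < 0 ||
              in >= snx || jn >= sny || kn >= snz) {
            out[idx] = fill;
            inside[idx] = false;
          } else {
            out[idx] = src[in + (R_xlen_t)snx * (jn + (R_xlen_t)sny * kn)];
            inside[idx] = true;
          }
        }
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Rasterize the straight segment p0 -> p1 (mm) onto the grid: sample the
// segment densely (step = min spacing / 4) and collect the voxels whose
// centres are nearest to each sample. Returns unique 1-based linear
// indices in order of first visit.
// [[Rcpp::export]]
IntegerVector cpp_segment_voxels(NumericVector p0, NumericVector p1,
                                 IntegerVector dim, NumericVector spacing,
                                 NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double len = 0;
  for (int c = 0; c < 3; ++c) {
    double d = p1[c] - p0[c];
    len += d * d;
  }
  len = std::sqrt(len);
  double step = std::min(spacing[0], std::min(spacing[1], spacing[2])) / 4.0;
  int nstep = std::max(1, (int)std::ceil(len / step));
  std::vector<int> res;
  R_xlen_t last = -1;
  std::set<R_xlen_t> seen;
  for (int s = 0; s <= nstep; ++s) {
    double t = (double)s / nstep;
    double px = p0[0] + t * (p1[0] - p0[0]);
    double py = p0[1] + t * (p1[1] - p0[1]);
    double pz = p0[2] + t * (p1[2] - p0[2]);
    int i = (int)std::lround((px - origin[0]) / spacing[0]);
    int j = (int)std::lround((py - origin[1]) / spacing[1]);
    int k = (int)std::lround((pz - origin[2]) / spacing[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
    R_xlen_t q = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    if (q == last) continue;
    if (seen.insert(q).second) res.push_back((int)(q + 1));
    last = q;
  }
  return wrap(res);
}
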