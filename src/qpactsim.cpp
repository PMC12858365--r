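// Compiled hot loops: voxel Monte Carlo photon transport, exact Euclidean
// distance transform, 26-connected component labelling, separable Gaussian
// blur, and batched symmetric 3x3 eigenvalues.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>
using namespace Rcpp;

// ----------------------------------------------------------------------------
// Deterministic RNG (xoshiro256+ seeded by splitmix64), independent of R's RNG
// so photon histories are bit-reproducible given the seed.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1): never exactly 0 (safe for log)
  inline double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }
};

inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

}  // namespace

// ----------------------------------------------------------------------------
// Monte Carlo fluence.
// mua, mus, g: voxel maps (mm^-1, mm^-1, unitless), column-major with dims.
// h: voxel size in mm; grid spans [0, n*h) per axis, voxel i covers [i*h,(i+1)*h).
// beams: rows (x, y, z, dx, dy, dz, half_angle_rad, weight). half_angle >= pi
// means isotropic emission. Continuous absorption weighting: at a collision the
// photon deposits mua/mut of its weight and scatters with the remainder
// (Henyey-Greenstein, local g); fluence accumulates track length x weight.
// [[Rcpp::export]]
List mc_run_cpp(NumericVector mua, NumericVector mus, NumericVector gvec,
                IntegerVector dims, double h, NumericMatrix beams,
                double n_photons, double roulette_wmin, double roulette_m,
                double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mua.size() != nvox || mus.size() != nvox || gvec.size() != nvox)
    stop("optical maps do not match grid dims");
  for (R_xlen_t i = 0; i < nvox; ++i)
    if (!R_finite(mua[i]) || !R_finite(mus[i]))
      stop("NaN/Inf in optical maps");
  NumericVector phi(nvox);
  Xoshiro rng((uint64_t)seed);

  const int nb = beams.nrow();
  std::vector<double> bw(nb);
  double wsum = 0.0;
  for (int b = 0; b < nb; ++b) { wsum += beams(b, 7); bw[b] = wsum; }
  if (wsum <= 0) stop("beam weights must sum > 0");

  const double Lx = nx * h, Ly = ny * h, Lz = nz * h;
  const double eps = 1e-9 * h;
  double absorbed = 0.0, escaped = 0.0, killed = 0.0, boost = 0.0;
  const double N = n_photons;
  const long maxsteps = 5000000L;

  for (double ip = 0; ip < N; ++ip) {
    // --- launch
    double u = rng.unif() * wsum;
    int b = 0;
    while (b < nb - 1 && u > bw[b]) ++b;
    double px = beams(b, 0), py = beams(b, 1), pz = beams(b, 2);
    double bx = beams(b, 3), by = beams(b, 4), bz = beams(b, 5);
    double ha = beams(b, 6);
    double dx, dy, dz;
    if (ha >= M_PI * 0.999) {  // isotropic
      double ct = 1.0 - 2.0 * rng.unif();
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph2 = 2.0 * M_PI * rng.unif();
      dx = st * std::cos(ph2); dy = st * std::sin(ph2); dz = ct;
    } else {
      // uniform solid angle within cone about beam axis
      double cmin = std::cos(ha);
      double ct = cmin + (1.0 - cmin) * rng.unif();
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph2 = 2.0 * M_PI * rng.unif();
      double lx = st * std::cos(ph2), ly = st * std::sin(ph2), lz = ct;
      // rotate local (0,0,1) frame onto beam axis
      double norm = std::sqrt(bx * bx + by * by + bz * bz);
      bx /= norm; by /= norm; bz /= norm;
      if (std::fabs(bz) > 0.999999) {
        double sgn = bz >= 0 ? 1.0 : -1.0;
        dx = sgn * lx; dy = sgn * ly; dz = sgn * lz;
      } else {
        double sz = std::sqrt(1.0 - bz * bz);
        dx = lx * bx * bz / sz - ly * by / sz + lz * bx;
        dy = lx * by * bz / sz + ly * bx / sz + lz * by;
        dz = -lx * sz + lz * bz;
      }
    }
    // --- advance to grid if launched outside (ray/box intersection)
    if (px < 0 || px >= Lx || py < 0 || py >= Ly || pz < 0 || pz >= Lz) {
      double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
      const double pmin[3] = {0, 0, 0}, pmax[3] = {Lx, Ly, Lz};
      const double pp[3] = {px, py, pz}, dd[3] = {dx, dy, dz};
      bool hit = true;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(dd[a]) < 1e-300) {
          if (pp[a] < pmin[a] || pp[a] >= pmax[a]) { hit = false; break; }
        } else {
          double ta = (pmin[a] - pp[a]) / dd[a];
          double tb = (pmax[a] - pp[a]) / dd[a];
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta); t1 = std::min(t1, tb);
          if (t0 > t1) { hit = false; break; }
        }
      }
      if (!hit) { escaped += 1.0; continue; }
      px += dx * (t0 + eps); py += dy * (t0 + eps); pz += dz * (t0 + eps);
      if (px < 0 || px >= Lx || py < 0 || py >= Ly || pz < 0 || pz >= Lz) {
        escaped += 1.0; continue;
      }
    }

    double w = 1.0;
    double tau = -std::log(rng.unif());
    long steps = 0;
    bool alive = true;
    while (alive) {
      if (++steps > maxsteps) { killed += w; break; }
      int ix = (int)std::floor(px / h), iy = (int)std::floor(py / h),
          iz = (int)std::floor(pz / h);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped += w; break;
      }
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      double ma = mua[idx], ms = mus[idx], mt = ma + ms;
      // distance to voxel boundary along dir
      double db = std::numeric_limits<double>::infinity();
      if (dx > 0) db = std::min(db, ((ix + 1) * h - px) / dx);
      else if (dx < 0) db = std::min(db, (ix * h - px) / dx);
      if (dy > 0) db = std::min(db, ((iy + 1) * h - py) / dy);
      else if (dy < 0) db = std::min(db, (iy * h - py) / dy);
      if (dz > 0) db = std::min(db, ((iz + 1) * h - pz) / dz);
      else if (dz < 0) db = std::min(db, (iz * h - pz) / dz);
      if (!(db > 0)) db = eps;

      if (mt <= 0.0) {  // transparent voxel: ballistic traversal
        phi[idx] += w * db;
        px += dx * (db + eps); py += dy * (db + eps); pz += dz * (db + eps);
        continue;
      }
      double dneed = tau / mt;
      if (dneed < db) {  // collision inside this voxel
        phi[idx] += w * dneed;
        px += dx * dneed; py += dy * dneed; pz += dz * dneed;
        absorbed += w * ma / mt;
        w *= ms / mt;
        if (w <= 0.0) break;  // fully absorbed (albedo 0)
        // scatter: Henyey-Greenstein with local g
        double gg = gvec[idx];
        double ct;
        if (std::fabs(gg) < 1e-6) ct = 1.0 - 2.0 * rng.unif();
        else {
          double f = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.unif());
          ct = (1.0 + gg * gg - f * f) / (2.0 * gg);
          ct = std::max(-1.0, std::min(1.0, ct));
        }
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double ph2 = 2.0 * M_PI * rng.unif();
        double cp = std::cos(ph2), sp = std::sin(ph2);
        if (std::fabs(dz) > 0.999999) {
          double sgn = dz >= 0 ? 1.0 : -1.0;
          dx = st * cp; dy = st * sp; dz = sgn * ct;
        } else {
          double sz = std::sqrt(1.0 - dz * dz);
          double ndx = st * (dx * dz * cp - dy * sp) / sz + dx * ct;
          double ndy = st * (dy * dz * cp + dx * sp) / sz + dy * ct;
          double ndz = -st * cp * sz + dz * ct;
          dx = ndx; dy = ndy; dz = ndz;
        }
        tau = -std::log(rng.unif());
        if (w < roulette_wmin) {  // Russian roulette
          if (rng.unif() < 1.0 / roulette_m) {
            boost += w * (roulette_m - 1.0);
            w *= roulette_m;
          } else { killed += w; break; }
        }
      } else {  // exits voxel before interacting
        phi[idx] += w * db;
        tau -= mt * db;
        px += dx * (db + eps); py += dy * (db + eps); pz += dz * (db + eps);
      }
    }
  }

  // track-length estimator: fluence per unit delivered energy (mm^-2)
  const double voxvol = h * h * h;
  for (R_xlen_t i = 0; i < nvox; ++i) phi[i] /= (N * voxvol);
  return List::create(_["phi"] = phi, _["launched"] = N,
                      _["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["killed"] = killed, _["boost"] = boost);
}

// ----------------------------------------------------------------------------
// Direct 3x3x3 "same" convolution kernels on (n_voxels x channels) feature
// matrices (zero padding), plus the two adjoints needed for backprop.
// Weight layout: W is (27*Cin x Cout), rows ordered offset-major
// (oz,oy,ox in {-1,0,1}), channel-minor.
namespace {
// copy channel `src` shifted by (ox,oy,oz) into buf (zero fill)
void shift_fill(const double* src, double* buf, int nx, int ny, int nz,
                int ox, int oy, int oz) {
  for (int z = 0; z < nz; ++z) {
    int zs = z + oz;
    for (int y = 0; y < ny; ++y) {
      int ys = y + oy;
      R_xlen_t dbase = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      if (zs < 0 || zs >= nz || ys < 0 || ys >= ny) {
        for (int x = 0; x < nx; ++x) buf[dbase + x] = 0.0;
        continue;
      }
      R_xlen_t sbase = (R_xlen_t)nx * (ys + (R_xlen_t)ny * zs);
      if (ox < 0) buf[dbase] = 0.0;
      if (ox > 0) buf[dbase + nx - 1] = 0.0;
      int x0 = (ox < 0) ? 1 : 0;
      int x1 = (ox > 0) ? nx - 1 : nx;
      for (int x = x0; x < x1; ++x) buf[dbase + x] = src[sbase + x + ox];
    }
  }
}
}  // namespace

// [[Rcpp::export]]
NumericMatrix conv3_fw_cpp(NumericMatrix X, IntegerVector dims,
                           NumericMatrix W, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int Cin = X.ncol(), Cout = W.ncol();
  if (X.nrow() != nv || W.nrow() != 27 * Cin) stop("conv3 shape mismatch");
  NumericMatrix Y(nv, Cout);
  std::vector<double> buf(nv);
  double* yp = Y.begin();
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + (R_xlen_t)co * nv;
    double bb = b[co];
    for (R_xlen_t v = 0; v < nv; ++v) yc[v] = bb;
  }
  int row = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox)
        for (int ci = 0; ci < Cin; ++ci, ++row) {
          shift_fill(X.begin() + (R_xlen_t)ci * nv, buf.data(),
                     nx, ny, nz, ox, oy, oz);
          for (int co = 0; co < Cout; ++co) {
            double w = W(row, co);
            if (w == 0.0) continue;
            double* yc = yp + (R_xlen_t)co * nv;
            for (R_xlen_t v = 0; v < nv; ++v) yc[v] += w * buf[v];
          }
        }
  return Y;
}

// gradient w.r.t. the input: correlation of dY with the flipped kernel
// [[Rcpp::export]]
NumericMatrix conv3_bwx_cpp(NumericMatrix dY, IntegerVector dims,
                            NumericMatrix W, int Cin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int Cout = dY.ncol();
  NumericMatrix dX(nv, Cin);
  std::vector<double> buf(nv);
  double* xp = dX.begin();
  int row = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        // adjoint: dX[v + o] += W[o] * dY[v]  <=>  dX[u] += W[o]*dY[u - o]
        for (int co = 0; co < Cout; ++co) {
          shift_fill(dY.begin() + (R_xlen_t)co * nv, buf.data(),
                     nx, ny, nz, -ox, -oy, -oz);
          for (int ci = 0; ci < Cin; ++ci) {
            double w = W(row + ci, co);
            if (w == 0.0) continue;
            double* xc = xp + (R_xlen_t)ci * nv;
            for (R_xlen_t v = 0; v < nv; ++v) xc[v] += w * buf[v];
          }
        }
        row += Cin;
      }
  return dX;
}

// gradient w.r.t. the weights
// [[Rcpp::export]]
NumericMatrix conv3_bww_cpp(NumericMatrix X, NumericMatrix dY,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int Cin = X.ncol(), Cout = dY.ncol();
  NumericMatrix dW(27 * Cin, Cout);
  std::vector<double> buf(nv);
  int row = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox)
        for (int ci = 0; ci < Cin; ++ci, ++row) {
          shift_fill(X.begin() + (R_xlen_t)ci * nv, buf.data(),
                     nx, ny, nz, ox, oy, oz);
          for (int co = 0; co < Cout; ++co) {
            const double* dyc = dY.begin() + (R_xlen_t)co * nv;
            double acc = 0.0;
            for (R_xlen_t v = 0; v < nv; ++v) acc += buf[v] * dyc[v];
            dW(row, co) = acc;
          }
        }
  return dW;
}

// ----------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3 passes
// of the 1D squared-distance transform. mask: 1 = foreground; returns, for
// every voxel, the distance (in voxels) to the nearest zero voxel (0 inside
// the background).
namespace {
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}
}  // namespace

// [[Rcpp::export]]
NumericVector edt3_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
            nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mask.size() != nvox) stop("mask does not match dims");
  const double INF = 1e30;
  std::vector<double> D(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) D[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      R_xlen_t base = (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
      for (int xi = 0; xi < nx; ++xi) f[xi] = D[base + xi];
      dt1d(f, d, nx, v, z);
      for (int xi = 0; xi < nx; ++xi) D[base + xi] = d[xi];
    }
  // y pass
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      for (int yi = 0; yi < ny; ++yi)
        f[yi] = D[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
      dt1d(f, d, ny, v, z);
      for (int yi = 0; yi < ny; ++yi)
        D[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)] = d[yi];
    }
  // z pass
  if (nz > 1)
    for (int yi = 0; yi < ny; ++yi)
      for (int xi = 0; xi < nx; ++xi) {
        for (int zi = 0; zi < nz; ++zi)
          f[zi] = D[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
        dt1d(f, d, nz, v, z);
        for (int zi = 0; zi < nz; ++zi)
          D[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)] = d[zi];
      }
  NumericVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = std::sqrt(D[i]);
  return out;
}

// ----------------------------------------------------------------------------
// 26-connected component labelling of a binary volume (iterative BFS).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
            nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mask.size() != nvox) stop("mask does not match dims");
  IntegerVector lab(nvox, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), zc = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz2 = -1; dz2 <= 1; ++dz2)
        for (int dy2 = -1; dy2 <= 1; ++dy2)
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            if (!dx2 && !dy2 && !dz2) continue;
            int xx = x + dx2, yy = y + dy2, zz = zc + dz2;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ----------------------------------------------------------------------------
// Separable Gaussian filtering with replicate boundary and optional
// derivative order (0, 1 or 2) per axis, matching the standard
// scale-space Gaussian-derivative construction.
namespace {
std::vector<double> gauss_kernel(double sigma, int order, int rad) {
  std::vector<double> ker(2 * rad + 1);
  double s2 = sigma * sigma, ks = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / s2);
    ks += ker[i + rad];
  }
  for (auto& k : ker) k /= ks;
  if (order == 1)
    for (int i = -rad; i <= rad; ++i) ker[i + rad] *= -i / s2;
  else if (order == 2)
    for (int i = -rad; i <= rad; ++i)
      ker[i + rad] *= (i * (double)i / s2 - 1.0) / s2;
  return ker;
}
}  // namespace

// [[Rcpp::export]]
NumericVector gauss_deriv3_cpp(NumericVector vol, IntegerVector dims,
                               double sigma, IntegerVector orders) {
  const int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
            nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (vol.size() != nvox) stop("volume does not match dims");
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> a(vol.begin(), vol.end()), bvec(nvox);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    if (n[axis] == 1) continue;
    int ord = axis < orders.size() ? orders[axis] : 0;
    std::vector<double> ker = gauss_kernel(sigma, ord, rad);
    for (R_xlen_t i = 0; i < nvox; ++i) {
      int pos = (int)((i / stride[axis]) % n[axis]);
      R_xlen_t base = i - (R_xlen_t)pos * stride[axis];
      double acc = 0;
      for (int k = -rad; k <= rad; ++k) {
        int pp = clampi(pos + k, 0, n[axis] - 1);
        acc += ker[k + rad] * a[base + (R_xlen_t)pp * stride[axis]];
      }
      bvec[i] = acc;
    }
    std::swap(a, bvec);
  }
  return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  return gauss_deriv3_cpp(vol, dims, sigma, IntegerVector::create(0, 0, 0));
}

// ----------------------------------------------------------------------------
// Batched eigenvalues of symmetric 3x3 matrices (trigonometric method),
// returned sorted by increasing |lambda| as the vesselness filter expects.
// [[Rcpp::export]]
NumericMatrix eig3_batch_cpp(NumericVector xx, NumericVector yy, NumericVector zz,
                             NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t n = xx.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = xx[i], b = yy[i], c = zz[i], d = xy[i], e = xz[i], f = yz[i];
    double l1, l2, l3;
    double p1 = d * d + e * e + f * f;
    if (p1 < 1e-300) { l1 = a; l2 = b; l3 = c; }
    else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double ba = (a - q) / p, bb = (b - q) / p, bc = (c - q) / p;
      double bd = d / p, be = e / p, bf = f / p;
      double detB = ba * (bb * bc - bf * bf) - bd * (bd * bc - bf * be) +
                    be * (bd * bf - bb * be);
      double r = detB / 2.0;
      r = std::max(-1.0, std::min(1.0, r));
      double phi = std::acos(r) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      l2 = 3.0 * q - l1 - l3;
    }
    // sort by |lambda| ascending
    double v[3] = {l1, l2, l3};
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(v[t]) > std::fabs(v[t + 1])) std::swap(v[t], v[t + 1]);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}
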