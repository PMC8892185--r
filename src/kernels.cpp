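// Low-level volumetric kernels.
//
// Feature maps are passed as C x V matrices (channels by voxels) with the
// voxel linear index v = x + nx*(y + ny*z), 0-based. Convolutions are
// expressed as im2col (vol2col) plus BLAS matrix products on the R side;
// the scatter/gather halves live here.

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Unfold a C x V feature map into a (27*C) x V column matrix for a 3x3x3
// convolution with zero padding 1. Row layout: offset-major, channel-minor
// (row = o*C + c, offsets ordered dz-major .. dx-minor).
// [[Rcpp::export(name = ".vol2col")]]
NumericMatrix vol2col(const NumericMatrix& x, const IntegerVector& dims) {
  const int C = x.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  NumericMatrix out(27 * C, V);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        const int v = lin(xx, y, z, nx, ny);
        double* col = op + (size_t)v * (27 * C);
        int o = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx, ++o) {
              const int sx = xx + dx, sy = y + dy, sz = z + dz;
              double* dst = col + (size_t)o * C;
              if (sx < 0 || sy < 0 || sz < 0 ||
                  sx >= nx || sy >= ny || sz >= nz) {
                for (int c = 0; c < C; ++c) dst[c] = 0.0;
              } else {
                const double* src = xp + (size_t)lin(sx, sy, sz, nx, ny) * C;
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
            }
      }
  return out;
}

// Adjoint of vol2col: fold a (27*C) x V column-gradient back onto the
// C x V input gradient (scatter-add).
// [[Rcpp::export(name = ".col2vol")]]
NumericMatrix col2vol(const NumericMatrix& dcol, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int C = dcol.nrow() / 27;
  NumericMatrix dx_(C, V);
  const double* gp = dcol.begin();
  double* dp = dx_.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        const int v = lin(xx, y, z, nx, ny);
        const double* col = gp + (size_t)v * (27 * C);
        int o = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dxo = -1; dxo <= 1; ++dxo, ++o) {
              const int sx = xx + dxo, sy = y + dy, sz = z + dz;
              if (sx < 0 || sy < 0 || sz < 0 ||
                  sx >= nx || sy >= ny || sz >= nz) continue;
              double* dst = dp + (size_t)lin(sx, sy, sz, nx, ny) * C;
              const double* src = col + (size_t)o * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
      }
  return dx_;
}

// 2x2x2 max pooling with stride 2. Returns the pooled C x V' map and the
// 0-based input voxel index of each maximum (for unpooling and backprop).
// [[Rcpp::export(name = ".maxpool2")]]
List maxpool2(const NumericMatrix& x, const IntegerVector& dims) {
  const int C = x.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int Vo = ox * oy * oz;
  NumericMatrix out(C, Vo);
  IntegerMatrix arg(C, Vo);
  const double* xp = x.begin();
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int xx = 0; xx < ox; ++xx) {
        const int vo = lin(xx, y, z, ox, oy);
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int bestv = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int v = lin(2 * xx + dx, 2 * y + dy, 2 * z + dz,
                                  nx, ny);
                const double val = xp[(size_t)v * C + c];
                if (val > best) { best = val; bestv = v; }
              }
          out(c, vo) = best;
          arg(c, vo) = bestv;
        }
      }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Index unpooling: place each value back at its recorded argmax voxel;
// all other voxels stay zero. Also serves as the pooling backward pass.
// [[Rcpp::export(name = ".maxunpool2")]]
NumericMatrix maxunpool2(const NumericMatrix& x, const IntegerMatrix& argmax,
                         const IntegerVector& dims_out) {
  const int C = x.nrow();
  const int V = dims_out[0] * dims_out[1] * dims_out[2];
  NumericMatrix out(C, V);
  for (int v = 0; v < x.ncol(); ++v)
    for (int c = 0; c < C; ++c)
      out(c, argmax(c, v)) += x(c, v);
  return out;
}

// ---- classical segmentation support ----------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zbuf, int n) {
  // 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance transform of a binary mask: for each
// foreground voxel, squared distance (voxel units) to the nearest
// background voxel. Background voxels get 0.
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(const IntegerVector& mask,
                          const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> g(V);
  for (int v = 0; v < V; ++v) g[v] = mask[v] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> vtx(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, vtx, zbuf, nx);
      for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, vtx, zbuf, ny);
      for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, vtx, zbuf, nz);
      for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
    }
  NumericVector out(V);
  for (int v = 0; v < V; ++v) out[v] = g[v];
  return out;
}

static void neighbor_offsets(int conn, int nx, int ny,
                             std::vector<std::array<int, 3> >& offs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int nz_ = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz_ == 0) continue;
        if (conn == 6 && nz_ != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }
  (void)nx; (void)ny;
}

// Marker-based watershed by priority flooding: voxels with the highest
// priority are claimed first, starting from the markers and growing only
// inside `region`. Returns a label volume (0 outside / unreached).
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(const NumericVector& priority,
                              const IntegerVector& markers,
                              const IntegerVector& region,
                              const IntegerVector& dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  IntegerVector labels(V);
  typedef std::tuple<double, long long, int> Item; // (-prio used? keep max)
  // max-heap on priority; FIFO counter (negated) breaks ties determin.
  std::priority_queue<Item> pq;
  long long counter = 0;
  for (int v = 0; v < V; ++v) {
    labels[v] = 0;
    if (markers[v] > 0 && region[v]) {
      labels[v] = markers[v];
      pq.push(Item(priority[v], -(counter++), v));
    }
  }
  std::vector<std::array<int, 3> > offs;
  neighbor_offsets(connectivity, nx, ny, offs);
  while (!pq.empty()) {
    const int v = std::get<2>(pq.top());
    pq.pop();
    const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (size_t k = 0; k < offs.size(); ++k) {
      const int sx = x + offs[k][0], sy = y + offs[k][1],
                sz = z + offs[k][2];
      if (sx < 0 || sy < 0 || sz < 0 || sx >= nx || sy >= ny || sz >= nz)
        continue;
      const int w = lin(sx, sy, sz, nx, ny);
      if (!region[w] || labels[w] != 0) continue;
      labels[w] = labels[v];
      pq.push(Item(priority[w], -(counter++), w));
    }
  }
  return labels;
}

// Connected-component labeling of a binary mask (BFS), labels 1..K in
// first-encounter order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(const IntegerVector& mask,
                               const IntegerVector& dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  IntegerVector labels(V);
  std::vector<std::array<int, 3> > offs;
  neighbor_offsets(connectivity, nx, ny, offs);
  int next = 0;
  std::vector<int> stack;
  for (int v0 = 0; v0 < V; ++v0) {
    if (!mask[v0] || labels[v0]) continue;
    ++next;
    labels[v0] = next;
    stack.push_back(v0);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        const int sx = x + offs[k][0], sy = y + offs[k][1],
                  sz = z + offs[k][2];
        if (sx < 0 || sy < 0 || sz < 0 || sx >= nx || sy >= ny || sz >= nz)
          continue;
        const int w = lin(sx, sy, sz, nx, ny);
        if (mask[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
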