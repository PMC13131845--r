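#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// All engine-side quantities are non-dimensional: lengths in units of the
// axon rest radius r0, time in units of r0/v0, forces in units of gamma_m*v0.

struct Beads {
  std::vector<double> x, y, z;
  std::vector<int> pid;  // unique particle id, never reused
  std::vector<int> cid;  // chain id, rewritten by fission/fusion
  std::vector<int> dir;  // +1 anterograde, -1 retrograde (per chain)
  int n() const { return static_cast<int>(x.size()); }
  void reserve(int m) {
    x.reserve(m); y.reserve(m); z.reserve(m);
    pid.reserve(m); cid.reserve(m); dir.reserve(m);
  }
  void push(double xi, double yi, double zi, int p, int c, int d) {
    x.push_back(xi); y.push_back(yi); z.push_back(zi);
    pid.push_back(p); cid.push_back(c); dir.push_back(d);
  }
};

// Beads of one chain occupy a contiguous block of rows in spring-bond order;
// bead j is bonded to j-1 and j+1 within [begin, end).
struct ChainRun { int begin, end; int len() const { return end - begin; } };

inline std::vector<ChainRun> chain_runs(const std::vector<int>& cid) {
  std::vector<ChainRun> runs;
  const int n = static_cast<int>(cid.size());
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && cid[j] == cid[i]) ++j;
    runs.push_back({i, j});
    i = j;
  }
  return runs;
}

struct Mesh {
  std::vector<double> x, y, z;
  std::vector<int> f1, f2, f3;              // faces, 0-based, outward-oriented
  std::vector<int> hi, hj, hk, hl;          // hinges: edge (i,j), wings k, l
  std::vector<int> sb1, sb2;                // spectrin bonds
  std::vector<double> s_rest;
  std::vector<int> ab1, ab2;                // actin bonds
  std::vector<double> a_rest;
  std::vector<int> mobile;                  // 1 = free node, 0 = pinned rim
  double A0 = 0.0;
  int n() const { return static_cast<int>(x.size()); }
  int nfaces() const { return static_cast<int>(f1.size()); }
  int nhinges() const { return static_cast<int>(hi.size()); }
};

// Uniform spatial hash over points; cell size >= interaction cutoff so a
// 27-cell stencil finds every pair within the cutoff (exactness contract).
struct CellGrid {
  double cell = 1.0, ox = 0.0, oy = 0.0, oz = 0.0;
  int nx = 1, ny = 1, nz = 1;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, double cellsize) {
    const int n = static_cast<int>(px.size());
    cell = cellsize;
    double x0 = 0, x1 = 0, y0 = 0, y1 = 0, z0 = 0, z1 = 0;
    if (n > 0) {
      x0 = x1 = px[0]; y0 = y1 = py[0]; z0 = z1 = pz[0];
      for (int i = 1; i < n; ++i) {
        if (px[i] < x0) x0 = px[i]; if (px[i] > x1) x1 = px[i];
        if (py[i] < y0) y0 = py[i]; if (py[i] > y1) y1 = py[i];
        if (pz[i] < z0) z0 = pz[i]; if (pz[i] > z1) z1 = pz[i];
      }
    }
    ox = x0; oy = y0; oz = z0;
    nx = std::max(1, static_cast<int>(std::floor((x1 - x0) / cell)) + 1);
    ny = std::max(1, static_cast<int>(std::floor((y1 - y0) / cell)) + 1);
    nz = std::max(1, static_cast<int>(std::floor((z1 - z0) / cell)) + 1);
    head.assign(static_cast<size_t>(nx) * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      const int c = cell_index(px[i], py[i], pz[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  int clampi(int v, int hi_) const { return v < 0 ? 0 : (v >= hi_ ? hi_ - 1 : v); }

  int cell_index(double X, double Y, double Z) const {
    const int ix = clampi(static_cast<int>(std::floor((X - ox) / cell)), nx);
    const int iy = clampi(static_cast<int>(std::floor((Y - oy) / cell)), ny);
    const int iz = clampi(static_cast<int>(std::floor((Z - oz) / cell)), nz);
    return (ix * ny + iy) * nz + iz;
  }

  // Visit all stored points within the 27-cell stencil around (X, Y, Z).
  template <typename F>
  void visit_neighbors(double X, double Y, double Z, F&& f) const {
    const int ix = static_cast<int>(std::floor((X - ox) / cell));
    const int iy = static_cast<int>(std::floor((Y - oy) / cell));
    const int iz = static_cast<int>(std::floor((Z - oz) / cell));
    for (int dx = -1; dx <= 1; ++dx) {
      const int cx = ix + dx; if (cx < 0 || cx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int cy = iy + dy; if (cy < 0 || cy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          const int cz = iz + dz; if (cz < 0 || cz >= nz) continue;
          for (int p = head[(cx * ny + cy) * nz + cz]; p >= 0; p = nxt[p]) f(p);
        }
      }
    }
  }
};

inline void vcross(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double vdot(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline double vnorm(const double a[3]) { return std::sqrt(vdot(a, a)); }
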