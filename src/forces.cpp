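#include "forces.h"
#include <limits>

static const double COINCIDENT_TOL = 1e-12;

// Quadratic bending energy U = kb/(8*rm) * theta^2 per interior triple
// (j, i, k), theta = arccos(t_i . t_{i+1}) with t_i = (r_i - r_j)/|.|,
// t_{i+1} = (r_k - r_i)/|.|; theta = 0 for a collinear triple. The force is
// the exact gradient, so the triple's three forces sum to zero.
void add_mito_bending(const Beads& b, const std::vector<ChainRun>& runs,
                      double kb_mito, double rm,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz) {
  const double pref = kb_mito / (4.0 * rm);
  for (const ChainRun& r : runs) {
    for (int i = r.begin + 1; i < r.end - 1; ++i) {
      const int j = i - 1, k = i + 1;
      const double u[3] = {b.x[i] - b.x[j], b.y[i] - b.y[j], b.z[i] - b.z[j]};
      const double v[3] = {b.x[k] - b.x[i], b.y[k] - b.y[i], b.z[k] - b.z[i]};
      const double lu = vnorm(u), lv = vnorm(v);
      if (lu < COINCIDENT_TOL || lv < COINCIDENT_TOL)
        Rcpp::stop("degenerate chain geometry: coincident bonded beads "
                   "(particles %d/%d/%d)", b.pid[j], b.pid[i], b.pid[k]);
      const double t1[3] = {u[0] / lu, u[1] / lu, u[2] / lu};
      const double t2[3] = {v[0] / lv, v[1] / lv, v[2] / lv};
      double c = vdot(t1, t2);
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      const double theta = std::acos(c);
      double s = std::sqrt(1.0 - c * c);
      // theta -> 0: theta/s -> 1 and grad(c) -> 0, so the force vanishes
      // smoothly; theta -> pi is a genuine fold-back, clamp s to stay finite.
      const double ratio = (s < 1e-8) ? 1.0 : theta / s;
      if (c < 0.0 && s < 1e-8) s = 1e-8;
      const double coef = pref * ratio;  // F_q = coef * d c / d r_q
      // d c / d u and d c / d v
      double gu[3], gv[3];
      for (int d = 0; d < 3; ++d) {
        gu[d] = (t2[d] - c * t1[d]) / lu;
        gv[d] = (t1[d] - c * t2[d]) / lv;
      }
      // r_j: -gu ; r_k: +gv ; r_i: gu - gv
      Fx[j] -= coef * gu[0]; Fy[j] -= coef * gu[1]; Fz[j] -= coef * gu[2];
      Fx[k] += coef * gv[0]; Fy[k] += coef * gv[1]; Fz[k] += coef * gv[2];
      Fx[i] += coef * (gu[0] - gv[0]);
      Fy[i] += coef * (gu[1] - gv[1]);
      Fz[i] += coef * (gu[2] - gv[2]);
    }
  }
}

// Pairwise Hookean bond: F_i = ks*(|r_ij| - 2*rm)*rhat_ij toward the partner
// when stretched, away when compressed.
void add_mito_springs(const Beads& b, const std::vector<ChainRun>& runs,
                      double ks_mito, double rm,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz) {
  const double rest = 2.0 * rm;
  for (const ChainRun& r : runs) {
    for (int i = r.begin; i < r.end - 1; ++i) {
      const int j = i + 1;
      const double d[3] = {b.x[j] - b.x[i], b.y[j] - b.y[i], b.z[j] - b.z[i]};
      const double L = vnorm(d);
      if (L < COINCIDENT_TOL)
        Rcpp::stop("degenerate chain geometry: coincident bonded beads "
                   "(particles %d/%d)", b.pid[i], b.pid[j]);
      const double f = ks_mito * (L - rest) / L;
      Fx[i] += f * d[0]; Fy[i] += f * d[1]; Fz[i] += f * d[2];
      Fx[j] -= f * d[0]; Fy[j] -= f * d[1]; Fz[j] -= f * d[2];
    }
  }
}

// Heaviside-gated Hookean repulsion between every bead pair except bonded
// intra-chain neighbours (2nd-nearest intra-chain neighbours DO interact).
// Pairs are found through a cell grid of cell size 2*rm (the interaction
// range), so no interacting pair is missed; each unordered pair is handled
// once (j > i).
void add_mito_steric(const Beads& b, double kM, double rm,
                     std::vector<double>& Fx, std::vector<double>& Fy,
                     std::vector<double>& Fz) {
  const int n = b.n();
  if (n < 2) return;
  const double rest = 2.0 * rm, rest2 = rest * rest;
  CellGrid grid;
  grid.build(b.x, b.y, b.z, rest);
  for (int i = 0; i < n; ++i) {
    grid.visit_neighbors(b.x[i], b.y[i], b.z[i], [&](int j) {
      if (j <= i) return;
      if (j == i + 1 && b.cid[i] == b.cid[j]) return;  // bonded pair
      const double d[3] = {b.x[j] - b.x[i], b.y[j] - b.y[i], b.z[j] - b.z[i]};
      const double L2 = vdot(d, d);
      if (L2 >= rest2) return;  // Heaviside gate closed
      const double L = std::sqrt(L2);
      if (L < COINCIDENT_TOL) return;  // undefined direction; zero is valid
      const double f = kM * (L - rest) / L;  // f < 0: push i away from j
      Fx[i] += f * d[0]; Fy[i] += f * d[1]; Fz[i] += f * d[2];
      Fx[j] -= f * d[0]; Fy[j] -= f * d[1]; Fz[j] -= f * d[2];
    });
  }
}

// Purely repulsive WCA force between a bead and a membrane node, length scale
// rm, cutoff 2^(1/6)*rm; magnitude (24*phi0/rm)*(2*q^-13 - q^-7), q = r/rm.
long add_wca(const Beads& b,
             const std::vector<double>& nx_, const std::vector<double>& ny_,
             const std::vector<double>& nz_, const CellGrid& grid,
             double phi0, double rm,
             std::vector<double>& Fbx, std::vector<double>& Fby,
             std::vector<double>& Fbz,
             std::vector<double>& Fnx, std::vector<double>& Fny,
             std::vector<double>& Fnz, bool accumulate_node) {
  const double cutoff = std::pow(2.0, 1.0 / 6.0) * rm;
  const double cutoff2 = cutoff * cutoff;
  const double pref = 24.0 * phi0 / rm;
  // magnitude clamp at r = 0.5*rm: bracket = 2*2^13 - 2^7
  const double capmag = pref * (2.0 * 8192.0 - 128.0);
  const double rcap = 0.5 * rm;
  long cap_hits = 0;
  const int n = b.n();
  // beads deeper inside the tube than (min node radius - cutoff) cannot be
  // within the cutoff of any node; skip their stencil visit (exactness kept)
  double rmin2 = std::numeric_limits<double>::max();
  for (size_t j = 0; j < nx_.size(); ++j) {
    const double r2 = ny_[j] * ny_[j] + nz_[j] * nz_[j];
    if (r2 < rmin2) rmin2 = r2;
  }
  const double rskip = std::sqrt(rmin2) - cutoff;
  const double rskip2 = rskip > 0.0 ? rskip * rskip : -1.0;
  for (int i = 0; i < n; ++i) {
    const double xi = b.x[i], yi = b.y[i], zi = b.z[i];
    if (yi * yi + zi * zi < rskip2) continue;
    grid.visit_neighbors(xi, yi, zi, [&](int j) {
      const double d[3] = {xi - nx_[j], yi - ny_[j], zi - nz_[j]};
      const double L2 = vdot(d, d);
      if (L2 >= cutoff2) return;
      const double L = std::sqrt(L2);
      double mag;
      if (L <= rcap) {
        mag = capmag;
        ++cap_hits;
      } else {
        const double q = L / rm;
        const double q2 = 1.0 / (q * q);
        const double q6 = q2 * q2 * q2;
        mag = pref * (2.0 * q6 * q6 / q - q6 / q);
      }
      double ux, uy, uz;
      if (L < COINCIDENT_TOL) { ux = 1.0; uy = 0.0; uz = 0.0; }  // capped anyway
      else { ux = d[0] / L; uy = d[1] / L; uz = d[2] / L; }
      Fbx[i] += mag * ux; Fby[i] += mag * uy; Fbz[i] += mag * uz;
      if (accumulate_node) {
        Fnx[j] -= mag * ux; Fny[j] -= mag * uy; Fnz[j] -= mag * uz;
      }
    });
  }
  return cap_hits;
}

// ---- membrane ----

// Hinge bending energy E = 2*kb*(e_ij/A_ij)*(1 - cos theta_ij) per interior
// edge (i,j) with wing vertices k (face i,j,k) and l (face j,i,l);
// A_ij = A_ijk + A_jil. The force is the exact energy gradient; its dominant
// term is 2*kb*(e/A)*sin(theta)*grad(theta).
void add_hinge_bending(const Mesh& m, const std::vector<double>& X,
                       const std::vector<double>& Y, const std::vector<double>& Z,
                       double kb,
                       std::vector<double>& Fx, std::vector<double>& Fy,
                       std::vector<double>& Fz) {
  const int nh = m.nhinges();
  for (int h = 0; h < nh; ++h) {
    const int i = m.hi[h], j = m.hj[h], k = m.hk[h], l = m.hl[h];
    const double pi_[3] = {X[i], Y[i], Z[i]}, pj[3] = {X[j], Y[j], Z[j]};
    const double pk[3] = {X[k], Y[k], Z[k]}, pl[3] = {X[l], Y[l], Z[l]};
    // face 1 = (i, j, k), face 2 = (j, i, l), both outward-oriented
    double e1[3], e2[3], N1[3], N2[3];
    for (int d = 0; d < 3; ++d) { e1[d] = pj[d] - pi_[d]; e2[d] = pk[d] - pi_[d]; }
    vcross(e1, e2, N1);
    double f1[3], f2[3];
    for (int d = 0; d < 3; ++d) { f1[d] = pi_[d] - pj[d]; f2[d] = pl[d] - pj[d]; }
    vcross(f1, f2, N2);
    const double n1m = vnorm(N1), n2m = vnorm(N2);
    if (n1m < 1e-14 || n2m < 1e-14)
      Rcpp::stop("degenerate (zero-area) triangle at hinge %d (nodes %d-%d)",
                 h + 1, i + 1, j + 1);
    double nh1[3], nh2[3];
    for (int d = 0; d < 3; ++d) { nh1[d] = N1[d] / n1m; nh2[d] = N2[d] / n2m; }
    double c = vdot(nh1, nh2);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    const double A = 0.5 * (n1m + n2m);        // A_ij = A1 + A2
    const double e = vnorm(e1);
    // gradients of c = nh1 . nh2
    double m1[3], m2[3];
    for (int d = 0; d < 3; ++d) {
      m1[d] = (nh2[d] - c * nh1[d]) / n1m;
      m2[d] = (nh1[d] - c * nh2[d]) / n2m;
    }
    // cyclic edge vectors w_v: triangle (a,b,c) -> w_a = b - c, etc.
    double w1i[3], w1j[3], w1k[3], w2j[3], w2i[3], w2l[3];
    for (int d = 0; d < 3; ++d) {
      w1i[d] = pj[d] - pk[d]; w1j[d] = pk[d] - pi_[d]; w1k[d] = pi_[d] - pj[d];
      w2j[d] = pi_[d] - pl[d]; w2i[d] = pl[d] - pj[d]; w2l[d] = pj[d] - pi_[d];
    }
    double gc[4][3] = {{0}};  // grad c wrt i, j, k, l
    double tmp[3];
    vcross(w1i, m1, tmp); for (int d = 0; d < 3; ++d) gc[0][d] += tmp[d];
    vcross(w1j, m1, tmp); for (int d = 0; d < 3; ++d) gc[1][d] += tmp[d];
    vcross(w1k, m1, tmp); for (int d = 0; d < 3; ++d) gc[2][d] += tmp[d];
    vcross(w2i, m2, tmp); for (int d = 0; d < 3; ++d) gc[0][d] += tmp[d];
    vcross(w2j, m2, tmp); for (int d = 0; d < 3; ++d) gc[1][d] += tmp[d];
    vcross(w2l, m2, tmp); for (int d = 0; d < 3; ++d) gc[3][d] += tmp[d];
    // grad A = 0.5*(w_v x nhat) per incident face
    double gA[4][3] = {{0}};
    vcross(w1i, nh1, tmp); for (int d = 0; d < 3; ++d) gA[0][d] += 0.5 * tmp[d];
    vcross(w1j, nh1, tmp); for (int d = 0; d < 3; ++d) gA[1][d] += 0.5 * tmp[d];
    vcross(w1k, nh1, tmp); for (int d = 0; d < 3; ++d) gA[2][d] += 0.5 * tmp[d];
    vcross(w2i, nh2, tmp); for (int d = 0; d < 3; ++d) gA[0][d] += 0.5 * tmp[d];
    vcross(w2j, nh2, tmp); for (int d = 0; d < 3; ++d) gA[1][d] += 0.5 * tmp[d];
    vcross(w2l, nh2, tmp); for (int d = 0; d < 3; ++d) gA[3][d] += 0.5 * tmp[d];
    // grad e: +ehat at j, -ehat at i
    double eh[3] = {e1[0] / e, e1[1] / e, e1[2] / e};
    const double one_m_c = 1.0 - c;
    const double ce = 2.0 * kb * one_m_c / A;        // coefficient of grad e
    const double cc = 2.0 * kb * e / A;              // coefficient of -grad c
    const double ca = 2.0 * kb * e * one_m_c / (A * A);  // coefficient of -grad A
    const int idx[4] = {i, j, k, l};
    for (int q = 0; q < 4; ++q) {
      const int v = idx[q];
      double ge[3] = {0, 0, 0};
      if (q == 0) { ge[0] = -eh[0]; ge[1] = -eh[1]; ge[2] = -eh[2]; }
      if (q == 1) { ge[0] = eh[0]; ge[1] = eh[1]; ge[2] = eh[2]; }
      Fx[v] += -ce * ge[0] + cc * gc[q][0] + ca * gA[q][0];
      Fy[v] += -ce * ge[1] + cc * gc[q][1] + ca * gA[q][1];
      Fz[v] += -ce * ge[2] + cc * gc[q][2] + ca * gA[q][2];
    }
  }
}

double total_mesh_area(const Mesh& m, const std::vector<double>& X,
                       const std::vector<double>& Y, const std::vector<double>& Z) {
  double A = 0.0;
  const int nf = m.nfaces();
  for (int f = 0; f < nf; ++f) {
    const int a = m.f1[f], b = m.f2[f], c = m.f3[f];
    const double u[3] = {X[b] - X[a], Y[b] - Y[a], Z[b] - Z[a]};
    const double v[3] = {X[c] - X[a], Y[c] - Y[a], Z[c] - Z[a]};
    double N[3];
    vcross(u, v, N);
    A += 0.5 * vnorm(N);
  }
  return A;
}

// Global area restoring force -(kAE/A0)*(A/A0 - 1) * sum_f grad_i A_f, the
// exact gradient of E = (kAE/2)*(A/A0 - 1)^2.
void add_area_elasticity(const Mesh& m, const std::vector<double>& X,
                         const std::vector<double>& Y, const std::vector<double>& Z,
                         double kAE,
                         std::vector<double>& Fx, std::vector<double>& Fy,
                         std::vector<double>& Fz) {
  if (m.A0 <= 0.0) Rcpp::stop("area elasticity requires A0 > 0");
  const double A = total_mesh_area(m, X, Y, Z);
  const double coef = (kAE / m.A0) * (A / m.A0 - 1.0);
  if (coef == 0.0) return;
  const int nf = m.nfaces();
  for (int f = 0; f < nf; ++f) {
    const int a = m.f1[f], b = m.f2[f], c = m.f3[f];
    const double pa[3] = {X[a], Y[a], Z[a]};
    const double pb[3] = {X[b], Y[b], Z[b]};
    const double pc[3] = {X[c], Y[c], Z[c]};
    double u[3], v[3], N[3];
    for (int d = 0; d < 3; ++d) { u[d] = pb[d] - pa[d]; v[d] = pc[d] - pa[d]; }
    vcross(u, v, N);
    const double nm = vnorm(N);
    if (nm < 1e-14)
      Rcpp::stop("degenerate (zero-area) face %d", f + 1);
    const double nh[3] = {N[0] / nm, N[1] / nm, N[2] / nm};
    double w[3], g[3];
    // grad_a A = 0.5*((pb - pc) x nhat), cyclic
    for (int d = 0; d < 3; ++d) w[d] = pb[d] - pc[d];
    vcross(w, nh, g);
    Fx[a] -= coef * 0.5 * g[0]; Fy[a] -= coef * 0.5 * g[1]; Fz[a] -= coef * 0.5 * g[2];
    for (int d = 0; d < 3; ++d) w[d] = pc[d] - pa[d];
    vcross(w, nh, g);
    Fx[b] -= coef * 0.5 * g[0]; Fy[b] -= coef * 0.5 * g[1]; Fz[b] -= coef * 0.5 * g[2];
    for (int d = 0; d < 3; ++d) w[d] = pa[d] - pb[d];
    vcross(w, nh, g);
    Fx[c] -= coef * 0.5 * g[0]; Fy[c] -= coef * 0.5 * g[1]; Fz[c] -= coef * 0.5 * g[2];
  }
}

// Hookean bond network (spectrin / actin): attracts when stretched beyond the
// per-bond rest length, repels when compressed.
void add_bond_springs(const std::vector<double>& X, const std::vector<double>& Y,
                      const std::vector<double>& Z, const std::vector<int>& b1,
                      const std::vector<int>& b2, const std::vector<double>& rest,
                      double k,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz) {
  const int nb = static_cast<int>(b1.size());
  for (int e = 0; e < nb; ++e) {
    const int i = b1[e], j = b2[e];
    const double d[3] = {X[j] - X[i], Y[j] - Y[i], Z[j] - Z[i]};
    const double L = vnorm(d);
    if (L < COINCIDENT_TOL)
      Rcpp::stop("degenerate bond: coincident nodes %d/%d", i + 1, j + 1);
    const double f = k * (L - rest[e]) / L;
    Fx[i] += f * d[0]; Fy[i] += f * d[1]; Fz[i] += f * d[2];
    Fx[j] -= f * d[0]; Fy[j] -= f * d[1]; Fz[j] -= f * d[2];
  }
}
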