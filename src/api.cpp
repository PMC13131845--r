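#include "forces.h"
#include "lifecycle.h"
#include "convert.h"

// Thin exported wrappers around the force/lifecycle kernels so that single
// operations can be exercised (and finite-difference checked) from R. Units
// are whatever consistent system the caller supplies.

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mito_bending(Rcpp::NumericMatrix pos,
                                     Rcpp::IntegerVector pid,
                                     Rcpp::IntegerVector cid,
                                     Rcpp::IntegerVector dir, double kb_mito,
                                     double rm) {
  Beads b = beads_from_r(pos, pid, cid, dir);
  std::vector<double> Fx(b.n(), 0.0), Fy(b.n(), 0.0), Fz(b.n(), 0.0);
  add_mito_bending(b, chain_runs(b.cid), kb_mito, rm, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mito_springs(Rcpp::NumericMatrix pos,
                                     Rcpp::IntegerVector pid,
                                     Rcpp::IntegerVector cid,
                                     Rcpp::IntegerVector dir, double ks_mito,
                                     double rm) {
  Beads b = beads_from_r(pos, pid, cid, dir);
  std::vector<double> Fx(b.n(), 0.0), Fy(b.n(), 0.0), Fz(b.n(), 0.0);
  add_mito_springs(b, chain_runs(b.cid), ks_mito, rm, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mito_steric(Rcpp::NumericMatrix pos,
                                    Rcpp::IntegerVector pid,
                                    Rcpp::IntegerVector cid,
                                    Rcpp::IntegerVector dir, double kM,
                                    double rm) {
  Beads b = beads_from_r(pos, pid, cid, dir);
  std::vector<double> Fx(b.n(), 0.0), Fy(b.n(), 0.0), Fz(b.n(), 0.0);
  add_mito_steric(b, kM, rm, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

// [[Rcpp::export]]
Rcpp::List cpp_wca(Rcpp::NumericMatrix bead_pos, Rcpp::NumericMatrix node_pos,
                   double phi0, double rm) {
  Beads b;
  b.reserve(bead_pos.nrow());
  for (int i = 0; i < bead_pos.nrow(); ++i)
    b.push(bead_pos(i, 0), bead_pos(i, 1), bead_pos(i, 2), i + 1, i + 1, 1);
  std::vector<double> nx_ = col_to_vec(node_pos, 0);
  std::vector<double> ny_ = col_to_vec(node_pos, 1);
  std::vector<double> nz_ = col_to_vec(node_pos, 2);
  CellGrid grid;
  const double cutoff = std::pow(2.0, 1.0 / 6.0) * rm;
  grid.build(nx_, ny_, nz_, cutoff);
  std::vector<double> Fbx(b.n(), 0.0), Fby(b.n(), 0.0), Fbz(b.n(), 0.0);
  std::vector<double> Fnx(nx_.size(), 0.0), Fny(nx_.size(), 0.0),
      Fnz(nx_.size(), 0.0);
  long caps = add_wca(b, nx_, ny_, nz_, grid, phi0, rm, Fbx, Fby, Fbz, Fnx,
                      Fny, Fnz, true);
  return Rcpp::List::create(Rcpp::Named("bead") = vecs_to_mat(Fbx, Fby, Fbz),
                            Rcpp::Named("node") = vecs_to_mat(Fnx, Fny, Fnz),
                            Rcpp::Named("cap_hits") = static_cast<double>(caps));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_membrane_bending(Rcpp::List mesh,
                                         Rcpp::NumericMatrix nodes, double kb) {
  Mesh m = mesh_from_r(mesh);
  m.x = col_to_vec(nodes, 0);
  m.y = col_to_vec(nodes, 1);
  m.z = col_to_vec(nodes, 2);
  std::vector<double> Fx(m.n(), 0.0), Fy(m.n(), 0.0), Fz(m.n(), 0.0);
  add_hinge_bending(m, m.x, m.y, m.z, kb, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_area_forces(Rcpp::List mesh, Rcpp::NumericMatrix nodes,
                                    double kAE) {
  Mesh m = mesh_from_r(mesh);
  m.x = col_to_vec(nodes, 0);
  m.y = col_to_vec(nodes, 1);
  m.z = col_to_vec(nodes, 2);
  std::vector<double> Fx(m.n(), 0.0), Fy(m.n(), 0.0), Fz(m.n(), 0.0);
  add_area_elasticity(m, m.x, m.y, m.z, kAE, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

// [[Rcpp::export]]
double cpp_mesh_area(Rcpp::List mesh, Rcpp::NumericMatrix nodes) {
  Mesh m = mesh_from_r(mesh);
  m.x = col_to_vec(nodes, 0);
  m.y = col_to_vec(nodes, 1);
  m.z = col_to_vec(nodes, 2);
  return total_mesh_area(m, m.x, m.y, m.z);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_bond_forces(Rcpp::NumericMatrix nodes,
                                    Rcpp::IntegerMatrix bonds,
                                    Rcpp::NumericVector rest, double k) {
  std::vector<double> X = col_to_vec(nodes, 0);
  std::vector<double> Y = col_to_vec(nodes, 1);
  std::vector<double> Z = col_to_vec(nodes, 2);
  std::vector<int> b1 = icol_to_vec0(bonds, 0);
  std::vector<int> b2 = icol_to_vec0(bonds, 1);
  std::vector<double> r(rest.begin(), rest.end());
  std::vector<double> Fx(X.size(), 0.0), Fy(X.size(), 0.0), Fz(X.size(), 0.0);
  add_bond_springs(X, Y, Z, b1, b2, r, k, Fx, Fy, Fz);
  return vecs_to_mat(Fx, Fy, Fz);
}

static Rcpp::List beads_to_r(const Beads& b,
                             const std::vector<LifecycleEvent>& ev,
                             long ring_skips) {
  const int n = b.n();
  Rcpp::NumericMatrix pos(n, 3);
  Rcpp::IntegerVector pid(n), cid(n), dir(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = b.x[i];
    pos(i, 1) = b.y[i];
    pos(i, 2) = b.z[i];
    pid[i] = b.pid[i];
    cid[i] = b.cid[i];
    dir[i] = b.dir[i];
  }
  const int ne = static_cast<int>(ev.size());
  Rcpp::NumericVector ev_t(ne), ev_x(ne);
  Rcpp::IntegerVector ev_type(ne), ev_a(ne), ev_b(ne);
  for (int i = 0; i < ne; ++i) {
    ev_t[i] = ev[i].t;
    ev_type[i] = ev[i].type;
    ev_a[i] = ev[i].id_a;
    ev_b[i] = ev[i].id_b;
    ev_x[i] = ev[i].xpos;
  }
  return Rcpp::List::create(
      Rcpp::Named("pos") = pos, Rcpp::Named("pid") = pid,
      Rcpp::Named("cid") = cid, Rcpp::Named("dir") = dir,
      Rcpp::Named("events") = Rcpp::List::create(
          Rcpp::Named("time") = ev_t, Rcpp::Named("type") = ev_type,
          Rcpp::Named("chain_a") = ev_a, Rcpp::Named("chain_b") = ev_b,
          Rcpp::Named("x") = ev_x),
      Rcpp::Named("ring_skips") = static_cast<double>(ring_skips));
}

// [[Rcpp::export]]
Rcpp::List cpp_fission_step(Rcpp::NumericMatrix pos, Rcpp::IntegerVector pid,
                            Rcpp::IntegerVector cid, Rcpp::IntegerVector dir,
                            double kfission, double dt, int next_cid,
                            double t) {
  Beads b = beads_from_r(pos, pid, cid, dir);
  std::vector<LifecycleEvent> ev;
  int nc = next_cid;
  fission_step_impl(b, kfission, dt, t, nc, ev);
  Rcpp::List out = beads_to_r(b, ev, 0);
  out["next_cid"] = nc;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_fusion_step(Rcpp::NumericMatrix pos, Rcpp::IntegerVector pid,
                           Rcpp::IntegerVector cid, Rcpp::IntegerVector dir,
                           double kfusion, double dt, double rfusion,
                           double cos_cutoff, double t) {
  Beads b = beads_from_r(pos, pid, cid, dir);
  std::vector<LifecycleEvent> ev;
  long ring_skips = 0;
  fusion_step_impl(b, kfusion, dt, rfusion, cos_cutoff, t, ev, ring_skips);
  return beads_to_r(b, ev, ring_skips);
}

// Radial placement used when generating mitochondria: uniform over the disk
// of the given radius (area-uniform r^2 law).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_sample_disk(int n, double rmax) {
  Rcpp::NumericMatrix yz(n, 2);
  for (int i = 0; i < n; ++i) {
    const double rr = rmax * std::sqrt(unif_rand());
    const double ang = 2.0 * M_PI * unif_rand();
    yz(i, 0) = rr * std::cos(ang);
    yz(i, 1) = rr * std::sin(ang);
  }
  return yz;
}
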