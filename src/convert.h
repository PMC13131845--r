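#pragma once
#include "sim_types.h"

inline std::vector<double> col_to_vec(const Rcpp::NumericMatrix& m, int j) {
  std::vector<double> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = m(i, j);
  return v;
}

inline std::vector<int> icol_to_vec0(const Rcpp::IntegerMatrix& m, int j) {
  // 1-based R indices -> 0-based
  std::vector<int> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = m(i, j) - 1;
  return v;
}

inline Beads beads_from_r(const Rcpp::NumericMatrix& pos,
                          const Rcpp::IntegerVector& pid,
                          const Rcpp::IntegerVector& cid,
                          const Rcpp::IntegerVector& dir) {
  Beads b;
  const int n = pos.nrow();
  b.reserve(n);
  for (int i = 0; i < n; ++i)
    b.push(pos(i, 0), pos(i, 1), pos(i, 2), pid[i], cid[i], dir[i]);
  return b;
}

inline Mesh mesh_from_r(const Rcpp::List& ml) {
  Mesh m;
  Rcpp::NumericMatrix nodes = ml["nodes"];
  m.x = col_to_vec(nodes, 0);
  m.y = col_to_vec(nodes, 1);
  m.z = col_to_vec(nodes, 2);
  Rcpp::IntegerMatrix faces = ml["faces"];
  m.f1 = icol_to_vec0(faces, 0);
  m.f2 = icol_to_vec0(faces, 1);
  m.f3 = icol_to_vec0(faces, 2);
  Rcpp::IntegerMatrix hinges = ml["hinges"];
  if (hinges.nrow() > 0) {
    m.hi = icol_to_vec0(hinges, 0);
    m.hj = icol_to_vec0(hinges, 1);
    m.hk = icol_to_vec0(hinges, 2);
    m.hl = icol_to_vec0(hinges, 3);
  }
  Rcpp::IntegerMatrix sb = ml["spectrin_bonds"];
  if (sb.nrow() > 0) {
    m.sb1 = icol_to_vec0(sb, 0);
    m.sb2 = icol_to_vec0(sb, 1);
    Rcpp::NumericVector sr = ml["spectrin_rest"];
    m.s_rest.assign(sr.begin(), sr.end());
  }
  Rcpp::IntegerMatrix ab = ml["actin_bonds"];
  if (ab.nrow() > 0) {
    m.ab1 = icol_to_vec0(ab, 0);
    m.ab2 = icol_to_vec0(ab, 1);
    Rcpp::NumericVector ar = ml["actin_rest"];
    m.a_rest.assign(ar.begin(), ar.end());
  }
  Rcpp::LogicalVector mob = ml["mobile"];
  m.mobile.assign(mob.begin(), mob.end());
  m.A0 = Rcpp::as<double>(ml["A0"]);
  return m;
}

inline Rcpp::NumericMatrix vecs_to_mat(const std::vector<double>& X,
                                       const std::vector<double>& Y,
                                       const std::vector<double>& Z) {
  const int n = static_cast<int>(X.size());
  Rcpp::NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = X[i];
    m(i, 1) = Y[i];
    m(i, 2) = Z[i];
  }
  return m;
}
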