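#include "lifecycle.h"

void fission_step_impl(Beads& b, double kfission, double dt, double t,
                       int& next_cid, std::vector<LifecycleEvent>& ev) {
  if (kfission <= 0.0) return;
  const std::vector<ChainRun> runs = chain_runs(b.cid);
  const double gate = dt * kfission;
  for (const ChainRun& r : runs) {
    const double p = unif_rand();  // one draw per chain, storage order
    if (gate < p) continue;
    const int len = r.len();
    if (len < 2) continue;  // singletons carry no bond to break
    int bond = static_cast<int>(std::floor(unif_rand() * (len - 1)));
    if (bond > len - 2) bond = len - 2;
    const int split = r.begin + bond + 1;  // first row of the new fragment
    const int parent = b.cid[r.begin];
    const int child = next_cid++;
    for (int i = split; i < r.end; ++i) b.cid[i] = child;
    const double xm = 0.5 * (b.x[split - 1] + b.x[split]);
    ev.push_back({t, 1, parent, child, xm});
  }
}

namespace {

struct EndBead {
  int row;       // row index of the end bead
  int chain;     // index into the run list
  int cid;
  int dir;
  double ux, uy, uz;  // end-to-end chain axis (unit), +x for singletons
};

struct Merge {
  int cid_a, pid_a;  // surviving chain and its fusing end bead
  int cid_b, pid_b;  // absorbed chain and its fusing end bead
  int newdir;
  double xpos;
};

// Re-orders the bead table so the merged chain is one contiguous block in
// bond order: A (fusing end last) followed by B (fusing end first).
void apply_merge(Beads& b, const Merge& mg) {
  const std::vector<ChainRun> runs = chain_runs(b.cid);
  int ia = -1, ib = -1;
  for (size_t r = 0; r < runs.size(); ++r) {
    if (b.cid[runs[r].begin] == mg.cid_a) ia = static_cast<int>(r);
    if (b.cid[runs[r].begin] == mg.cid_b) ib = static_cast<int>(r);
  }
  if (ia < 0 || ib < 0) Rcpp::stop("internal error: fusion chain vanished");
  const ChainRun ra = runs[ia], rb = runs[ib];
  std::vector<int> order;
  order.reserve(b.n());
  auto emit_chain = [&](const ChainRun& r, int end_pid, bool end_last) {
    const bool at_begin = (b.pid[r.begin] == end_pid);
    const bool forward = end_last ? !at_begin : at_begin;
    if (forward)
      for (int i = r.begin; i < r.end; ++i) order.push_back(i);
    else
      for (int i = r.end - 1; i >= r.begin; --i) order.push_back(i);
  };
  for (size_t r = 0; r < runs.size(); ++r) {
    if (static_cast<int>(r) == ib) continue;
    if (static_cast<int>(r) == ia) {
      emit_chain(ra, mg.pid_a, true);
      emit_chain(rb, mg.pid_b, false);
    } else {
      for (int i = runs[r].begin; i < runs[r].end; ++i) order.push_back(i);
    }
  }
  Beads nb;
  nb.reserve(b.n());
  for (int i : order)
    nb.push(b.x[i], b.y[i], b.z[i], b.pid[i], b.cid[i], b.dir[i]);
  // relabel the merged block
  for (int i = 0; i < nb.n(); ++i) {
    if (nb.cid[i] == mg.cid_b) nb.cid[i] = mg.cid_a;
  }
  for (int i = 0; i < nb.n(); ++i) {
    if (nb.cid[i] == mg.cid_a) nb.dir[i] = mg.newdir;
  }
  b = std::move(nb);
}

}  // namespace

void fusion_step_impl(Beads& b, double kfusion, double dt, double rfusion,
                      double cos_cutoff, double t,
                      std::vector<LifecycleEvent>& ev, long& ring_skips) {
  if (kfusion <= 0.0) return;
  const std::vector<ChainRun> runs = chain_runs(b.cid);
  std::vector<EndBead> ends;
  ends.reserve(2 * runs.size());
  for (size_t r = 0; r < runs.size(); ++r) {
    const ChainRun& cr = runs[r];
    double ux = b.dir[cr.begin], uy = 0.0, uz = 0.0;
    if (cr.len() > 1) {
      ux = b.x[cr.end - 1] - b.x[cr.begin];
      uy = b.y[cr.end - 1] - b.y[cr.begin];
      uz = b.z[cr.end - 1] - b.z[cr.begin];
      const double nm = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (nm > 1e-12) { ux /= nm; uy /= nm; uz /= nm; }
      else { ux = b.dir[cr.begin]; uy = 0.0; uz = 0.0; }
    }
    ends.push_back({cr.begin, static_cast<int>(r), b.cid[cr.begin],
                    b.dir[cr.begin], ux, uy, uz});
    if (cr.len() > 1)
      ends.push_back({cr.end - 1, static_cast<int>(r), b.cid[cr.begin],
                      b.dir[cr.begin], ux, uy, uz});
  }
  // geometric prefilter: end-bead pairs within the fusion radius
  const double r2 = rfusion * rfusion;
  std::vector<std::pair<int, int>> cand;
  const int ne = static_cast<int>(ends.size());
  for (int a = 0; a < ne; ++a) {
    for (int c = a + 1; c < ne; ++c) {
      const double dx = b.x[ends[a].row] - b.x[ends[c].row];
      const double dy = b.y[ends[a].row] - b.y[ends[c].row];
      const double dz = b.z[ends[a].row] - b.z[ends[c].row];
      if (dx * dx + dy * dy + dz * dz <= r2) cand.emplace_back(a, c);
    }
  }
  if (cand.empty()) return;
  // shuffled visiting order removes pair-iteration bias
  for (int a = static_cast<int>(cand.size()) - 1; a > 0; --a) {
    int j = static_cast<int>(std::floor(unif_rand() * (a + 1)));
    if (j > a) j = a;
    std::swap(cand[a], cand[j]);
  }
  const double gate = dt * kfusion;
  std::vector<bool> used(runs.size(), false);
  std::vector<Merge> merges;
  for (const auto& pr : cand) {
    const EndBead& ea = ends[pr.first];
    const EndBead& eb = ends[pr.second];
    if (ea.chain == eb.chain) {  // would form a ring
      ++ring_skips;
      ev.push_back({t, 3, ea.cid, eb.cid,
                    0.5 * (b.x[ea.row] + b.x[eb.row])});
      continue;
    }
    if (used[ea.chain] || used[eb.chain]) continue;
    // nematic orientation difference between chain axes
    const double cang = std::fabs(ea.ux * eb.ux + ea.uy * eb.uy + ea.uz * eb.uz);
    if (cang < cos_cutoff) continue;
    const double p = unif_rand();
    if (gate < p) continue;
    int newdir;
    if (ea.dir == eb.dir) newdir = ea.dir;
    else newdir = (unif_rand() < 0.5) ? 1 : -1;
    used[ea.chain] = used[eb.chain] = true;
    merges.push_back({ea.cid, b.pid[ea.row], eb.cid, b.pid[eb.row], newdir,
                      0.5 * (b.x[ea.row] + b.x[eb.row])});
  }
  for (const Merge& mg : merges) {
    apply_merge(b, mg);
    ev.push_back({t, 2, mg.cid_a, mg.cid_b, mg.xpos});
  }
}
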