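#include "forces.h"
#include "lifecycle.h"
#include "convert.h"
#include <limits>

// Full simulation protocol, non-dimensional units throughout (lengths r0,
// times r0/v0, forces gamma_m*v0). Per step: (1) generate mitochondria on
// both ends at the configured cadence until the bead budget is exhausted,
// (2) stochastic fission/fusion, (3) assemble bead and membrane forces,
// (4) forward-Euler overdamped update, (5) remove beads that left the axon,
// (6) record frames/metrics every output interval.
//
// RNG discipline (single R stream, documented order): per spawn tick the
// anterograde then the retrograde side each consume exactly
// 2*max_attempts uniforms (candidate radial positions), independent of how
// many candidates are inspected; fission draws one uniform per chain plus
// one per split; fusion draws shuffle + gate + direction uniforms. No draws
// occur for a lifecycle process whose rate is zero, or for a side whose
// spawn is blocked by the budget.

namespace {

struct EngineCfg {
  double dt;
  int n_steps, output_every, mesh_stride, cadence_steps;
  int n_chain, budget, initial_pairs, max_attempts;
  bool refill, deformable, record_mesh, spawn_force;
  double L, rm, r_spawn, va, vr, gamma_m, gamma_a;
  double kb_mito, ks_mito, kM, phi0;
  double kb_mem, kAE, kS, kA;
  double kfission, kfusion, rfusion, cos_cutoff;
  double instab_disp;
};

EngineCfg read_cfg(const Rcpp::List& cfg) {
  EngineCfg c;
  c.dt = cfg["dt"];
  c.n_steps = cfg["n_steps"];
  c.output_every = cfg["output_every"];
  c.mesh_stride = cfg["mesh_stride"];
  c.cadence_steps = cfg["cadence_steps"];
  c.n_chain = cfg["n_chain"];
  c.budget = cfg["budget"];
  c.initial_pairs = cfg["initial_pairs"];
  c.max_attempts = cfg["max_attempts"];
  c.refill = cfg["refill"];
  c.spawn_force = cfg["spawn_force"];
  c.deformable = cfg["deformable"];
  c.record_mesh = cfg["record_mesh"];
  c.L = cfg["L"];
  c.rm = cfg["rm"];
  c.r_spawn = cfg["r_spawn"];
  c.va = cfg["va"];
  c.vr = cfg["vr"];
  c.gamma_m = cfg["gamma_m"];
  c.gamma_a = cfg["gamma_a"];
  c.kb_mito = cfg["kb_mito"];
  c.ks_mito = cfg["ks_mito"];
  c.kM = cfg["kM"];
  c.phi0 = cfg["phi0"];
  c.kb_mem = cfg["kb_mem"];
  c.kAE = cfg["kAE"];
  c.kS = cfg["kS"];
  c.kA = cfg["kA"];
  c.kfission = cfg["kfission"];
  c.kfusion = cfg["kfusion"];
  c.rfusion = cfg["rfusion"];
  c.cos_cutoff = cfg["cos_cutoff"];
  c.instab_disp = cfg["instab_disp"];
  if (c.dt <= 0) Rcpp::stop("dt must be positive");
  return c;
}

class Engine {
 public:
  Engine(const EngineCfg& c, const Rcpp::List& meshList)
      : cfg(c), mesh(mesh_from_r(meshList)) {
    cutoff = std::pow(2.0, 1.0 / 6.0) * cfg.rm;
    grid.build(mesh.x, mesh.y, mesh.z, cutoff);
    next_pid = 1;
    next_cid = 1;
    spawned_beads = 0;
    escaped_beads = 0;
    spawn_deferrals = 0;
    forced_spawns = 0;
    wca_cap_hits = 0;
    ring_skips = 0;
  }

  Rcpp::List run() {
    const int n_out = cfg.n_steps / cfg.output_every + 1;
    times.reserve(n_out);
    frames = Rcpp::List(n_out);
    dilation.reserve(n_out);
    spawned_log.reserve(n_out);
    escaped_log.reserve(n_out);
    // initial generation: initial_pairs chains per side
    for (int p = 0; p < cfg.initial_pairs; ++p) {
      try_spawn(+1);
      try_spawn(-1);
    }
    record(0, 0.0);
    for (int step = 1; step <= cfg.n_steps; ++step) {
      const double t = step * cfg.dt;
      if (cfg.cadence_steps > 0 && step % cfg.cadence_steps == 0) {
        try_spawn(+1);
        try_spawn(-1);
      }
      fission_step_impl(beads, cfg.kfission, cfg.dt, t, next_cid, events);
      fusion_step_impl(beads, cfg.kfusion, cfg.dt, cfg.rfusion,
                       cfg.cos_cutoff, t, events, ring_skips);
      compute_forces();
      advance(step);
      remove_escaped();
      if (step % cfg.output_every == 0)
        record(step / cfg.output_every, t);
      if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    }
    return collect();
  }

 private:
  EngineCfg cfg;
  Mesh mesh;
  CellGrid grid;
  double cutoff;
  Beads beads;
  int next_pid, next_cid;
  long spawned_beads, escaped_beads, spawn_deferrals, forced_spawns,
      wca_cap_hits, ring_skips;
  std::vector<LifecycleEvent> events;
  // per-term bead force accumulators (kept separate for diagnostics)
  std::vector<double> fbx, fby, fbz, fsx, fsy, fsz, ftx, fty, ftz, fwx, fwy, fwz;
  std::vector<double> gx, gy, gz;  // totals
  // membrane force accumulators
  std::vector<double> mbx, mby, mbz, max_, may_, maz_, mcx, mcy, mcz, mwx, mwy,
      mwz, mgx, mgy, mgz;
  // output buffers
  std::vector<double> times, dilation;
  std::vector<long> spawned_log, escaped_log;
  Rcpp::List frames;
  std::vector<double> mesh_times;
  std::vector<Rcpp::NumericMatrix> mesh_frames;

  bool try_spawn(int dir) {
    const bool room = cfg.refill
        ? (beads.n() + cfg.n_chain <= cfg.budget)
        : (spawned_beads + cfg.n_chain <= cfg.budget);
    if (!room) return false;
    // fixed RNG budget: always draw max_attempts candidate (y, z) positions
    std::vector<double> cy(cfg.max_attempts), cz(cfg.max_attempts);
    for (int a = 0; a < cfg.max_attempts; ++a) {
      const double rr = cfg.r_spawn * std::sqrt(unif_rand());
      const double ang = 2.0 * M_PI * unif_rand();
      cy[a] = rr * std::cos(ang);
      cz[a] = rr * std::sin(ang);
    }
    const double x0 = (dir > 0) ? 0.0 : cfg.L;
    const double dx = (dir > 0) ? 2.0 * cfg.rm : -2.0 * cfg.rm;
    const double min2 = 4.0 * cfg.rm * cfg.rm;
    int best = -1;
    double best_d2 = -1.0;
    for (int a = 0; a < cfg.max_attempts; ++a) {
      double d2min = std::numeric_limits<double>::max();
      for (int q = 0; q < cfg.n_chain; ++q) {
        const double px = x0 + q * dx;
        for (int i = 0; i < beads.n(); ++i) {
          const double ddx = beads.x[i] - px, ddy = beads.y[i] - cy[a],
                       ddz = beads.z[i] - cz[a];
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < d2min) d2min = d2;
        }
      }
      if (d2min > best_d2) { best_d2 = d2min; best = a; }
      if (d2min >= min2) { best = a; best_d2 = d2min; break; }  // no overlap
    }
    const bool overlaps = best_d2 < min2;
    if (overlaps) {
      if (!cfg.spawn_force) {
        ++spawn_deferrals;  // retried at the next cadence tick
        return false;
      }
      // least-overlapping placement; the steric term resolves the overlap
      ++forced_spawns;
    }
    const int cid = next_cid++;
    for (int q = 0; q < cfg.n_chain; ++q)
      beads.push(x0 + q * dx, cy[best], cz[best], next_pid++, cid, dir);
    spawned_beads += cfg.n_chain;
    return true;
  }

  void resize_bead_arrays() {
    const size_t n = beads.x.size();
    for (auto* v : {&fbx, &fby, &fbz, &fsx, &fsy, &fsz, &ftx, &fty, &ftz,
                    &fwx, &fwy, &fwz, &gx, &gy, &gz})
      v->assign(n, 0.0);
  }

  void resize_node_arrays() {
    const size_t n = mesh.x.size();
    for (auto* v : {&mbx, &mby, &mbz, &max_, &may_, &maz_, &mcx, &mcy, &mcz,
                    &mwx, &mwy, &mwz, &mgx, &mgy, &mgz})
      v->assign(n, 0.0);
  }

  void compute_forces() {
    resize_bead_arrays();
    const std::vector<ChainRun> runs = chain_runs(beads.cid);
    if (cfg.kb_mito > 0) add_mito_bending(beads, runs, cfg.kb_mito, cfg.rm, fbx, fby, fbz);
    add_mito_springs(beads, runs, cfg.ks_mito, cfg.rm, fsx, fsy, fsz);
    add_mito_steric(beads, cfg.kM, cfg.rm, ftx, fty, ftz);
    if (cfg.deformable) {
      resize_node_arrays();
      grid.build(mesh.x, mesh.y, mesh.z, cutoff);
      wca_cap_hits += add_wca(beads, mesh.x, mesh.y, mesh.z, grid, cfg.phi0,
                              cfg.rm, fwx, fwy, fwz, mwx, mwy, mwz, true);
      add_hinge_bending(mesh, mesh.x, mesh.y, mesh.z, cfg.kb_mem, mbx, mby, mbz);
      add_area_elasticity(mesh, mesh.x, mesh.y, mesh.z, cfg.kAE, max_, may_, maz_);
      add_bond_springs(mesh.x, mesh.y, mesh.z, mesh.sb1, mesh.sb2, mesh.s_rest,
                       cfg.kS, mcx, mcy, mcz);
      add_bond_springs(mesh.x, mesh.y, mesh.z, mesh.ab1, mesh.ab2, mesh.a_rest,
                       cfg.kA, mcx, mcy, mcz);
      for (size_t i = 0; i < mesh.x.size(); ++i) {
        mgx[i] = mbx[i] + max_[i] + mcx[i] + mwx[i];
        mgy[i] = mby[i] + may_[i] + mcy[i] + mwy[i];
        mgz[i] = mbz[i] + maz_[i] + mcz[i] + mwz[i];
      }
    } else {
      // static wall: bead side of the WCA interaction only
      wca_cap_hits += add_wca(beads, mesh.x, mesh.y, mesh.z, grid, cfg.phi0,
                              cfg.rm, fwx, fwy, fwz, mwx, mwy, mwz, false);
    }
    for (int i = 0; i < beads.n(); ++i) {
      gx[i] = fbx[i] + fsx[i] + ftx[i] + fwx[i];
      gy[i] = fby[i] + fsy[i] + fty[i] + fwy[i];
      gz[i] = fbz[i] + fsz[i] + ftz[i] + fwz[i];
    }
  }

  void instability_abort(int step, int i) {
    const double nb = std::sqrt(fbx[i] * fbx[i] + fby[i] * fby[i] + fbz[i] * fbz[i]);
    const double ns = std::sqrt(fsx[i] * fsx[i] + fsy[i] * fsy[i] + fsz[i] * fsz[i]);
    const double nt = std::sqrt(ftx[i] * ftx[i] + fty[i] * fty[i] + ftz[i] * ftz[i]);
    const double nw = std::sqrt(fwx[i] * fwx[i] + fwy[i] * fwy[i] + fwz[i] * fwz[i]);
    const char* term = "bending";
    double mx = nb;
    if (ns > mx) { mx = ns; term = "spring"; }
    if (nt > mx) { mx = nt; term = "steric"; }
    if (nw > mx) { mx = nw; term = "membrane WCA"; }
    Rcpp::stop("numerical instability at step %d: bead %d moved more than rm "
               "in one step (dominant force term: %s, |F| = %g); reduce dt",
               step, beads.pid[i], term, mx);
  }

  void advance(int step) {
    const double dt = cfg.dt;
    const double lim2 = cfg.instab_disp * cfg.instab_disp;
    for (int i = 0; i < beads.n(); ++i) {
      const double vprop = (beads.dir[i] > 0) ? cfg.va : -cfg.vr;
      const double ddx = dt * (gx[i] / cfg.gamma_m + vprop);
      const double ddy = dt * (gy[i] / cfg.gamma_m);
      const double ddz = dt * (gz[i] / cfg.gamma_m);
      if (ddx * ddx + ddy * ddy + ddz * ddz > lim2) instability_abort(step, i);
      beads.x[i] += ddx;
      beads.y[i] += ddy;
      beads.z[i] += ddz;
    }
    if (cfg.deformable) {
      for (size_t i = 0; i < mesh.x.size(); ++i) {
        if (!mesh.mobile[i]) continue;
        const double ddx = dt * mgx[i] / cfg.gamma_a;
        const double ddy = dt * mgy[i] / cfg.gamma_a;
        const double ddz = dt * mgz[i] / cfg.gamma_a;
        if (ddx * ddx + ddy * ddy + ddz * ddz > lim2)
          Rcpp::stop("numerical instability at step %d: membrane node %d "
                     "moved more than rm in one step; reduce dt",
                     step, static_cast<int>(i) + 1);
        mesh.x[i] += ddx;
        mesh.y[i] += ddy;
        mesh.z[i] += ddz;
      }
    }
  }

  void remove_escaped() {
    bool any = false;
    for (int i = 0; i < beads.n(); ++i) {
      if (beads.x[i] < 0.0 || beads.x[i] > cfg.L) { any = true; break; }
    }
    if (!any) return;
    const std::vector<ChainRun> runs = chain_runs(beads.cid);
    Beads nb;
    nb.reserve(beads.n());
    for (const ChainRun& r : runs) {
      bool fragment_open = false;   // currently emitting a kept fragment
      bool first_fragment = true;
      int cur_cid = beads.cid[r.begin];
      for (int i = r.begin; i < r.end; ++i) {
        const bool keep = (beads.x[i] >= 0.0 && beads.x[i] <= cfg.L);
        if (!keep) {
          ++escaped_beads;
          fragment_open = false;
          continue;
        }
        if (!fragment_open) {
          // an interior removal splits the chain: later fragments get new ids
          if (!first_fragment) cur_cid = next_cid++;
          first_fragment = false;
          fragment_open = true;
        }
        nb.push(beads.x[i], beads.y[i], beads.z[i], beads.pid[i], cur_cid,
                beads.dir[i]);
      }
    }
    beads = std::move(nb);
  }

  void record(int out_idx, double t) {
    times.push_back(t);
    const int n = beads.n();
    Rcpp::NumericMatrix pos(n, 3);
    Rcpp::IntegerVector pid(n), cid(n), dir(n);
    for (int i = 0; i < n; ++i) {
      pos(i, 0) = beads.x[i];
      pos(i, 1) = beads.y[i];
      pos(i, 2) = beads.z[i];
      pid[i] = beads.pid[i];
      cid[i] = beads.cid[i];
      dir[i] = beads.dir[i];
    }
    frames[out_idx] = Rcpp::List::create(
        Rcpp::Named("pos") = pos, Rcpp::Named("pid") = pid,
        Rcpp::Named("cid") = cid, Rcpp::Named("dir") = dir);
    // max radial dilation over mobile nodes (radius is 1 in these units)
    double mx = 0.0;
    for (size_t i = 0; i < mesh.x.size(); ++i) {
      if (!mesh.mobile[i]) continue;
      const double rr = std::sqrt(mesh.y[i] * mesh.y[i] + mesh.z[i] * mesh.z[i]) - 1.0;
      if (rr > mx) mx = rr;
    }
    dilation.push_back(mx);
    spawned_log.push_back(spawned_beads);
    escaped_log.push_back(escaped_beads);
    if (cfg.record_mesh &&
        (out_idx % cfg.mesh_stride == 0 || out_idx == cfg.n_steps / cfg.output_every)) {
      mesh_times.push_back(t);
      mesh_frames.push_back(vecs_to_mat(mesh.x, mesh.y, mesh.z));
    }
  }

  Rcpp::List collect() {
    const int ne = static_cast<int>(events.size());
    Rcpp::NumericVector ev_t(ne), ev_x(ne);
    Rcpp::IntegerVector ev_type(ne), ev_a(ne), ev_b(ne);
    for (int i = 0; i < ne; ++i) {
      ev_t[i] = events[i].t;
      ev_type[i] = events[i].type;
      ev_a[i] = events[i].id_a;
      ev_b[i] = events[i].id_b;
      ev_x[i] = events[i].xpos;
    }
    Rcpp::List mf(mesh_frames.size());
    for (size_t i = 0; i < mesh_frames.size(); ++i) mf[i] = mesh_frames[i];
    return Rcpp::List::create(
        Rcpp::Named("times") = times,
        Rcpp::Named("frames") = frames,
        Rcpp::Named("dilation") = dilation,
        Rcpp::Named("spawned") = spawned_log,
        Rcpp::Named("escaped") = escaped_log,
        Rcpp::Named("mesh_times") = mesh_times,
        Rcpp::Named("mesh_frames") = mf,
        Rcpp::Named("final_mesh") = vecs_to_mat(mesh.x, mesh.y, mesh.z),
        Rcpp::Named("events") = Rcpp::List::create(
            Rcpp::Named("time") = ev_t, Rcpp::Named("type") = ev_type,
            Rcpp::Named("chain_a") = ev_a, Rcpp::Named("chain_b") = ev_b,
            Rcpp::Named("x") = ev_x),
        Rcpp::Named("diagnostics") = Rcpp::List::create(
            Rcpp::Named("wca_cap_hits") = static_cast<double>(wca_cap_hits),
            Rcpp::Named("spawn_deferrals") = static_cast<double>(spawn_deferrals),
            Rcpp::Named("forced_spawns") = static_cast<double>(forced_spawns),
            Rcpp::Named("ring_skips") = static_cast<double>(ring_skips)));
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run_simulation(Rcpp::List cfg, Rcpp::List mesh) {
  Engine eng(read_cfg(cfg), mesh);
  return eng.run();
}
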