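#pragma once
#include "sim_types.h"

struct LifecycleEvent {
  double t;
  int type;     // 1 = fission, 2 = fusion, 3 = ring attempt skipped
  int id_a;     // fission: parent chain; fusion: surviving chain
  int id_b;     // fission: new chain; fusion: absorbed chain
  double xpos;  // axial location of the split bond / fused junction
};

// Per-chain fission gate: one uniform draw per chain per step; a chain with
// dt*k_fission >= p splits at a uniformly chosen internal bond, the downstream
// fragment receiving a fresh chain id. Draws come from R's RNG stream.
void fission_step_impl(Beads& b, double kfission, double dt, double t,
                       int& next_cid, std::vector<LifecycleEvent>& ev);

// End-bead fusion: candidate pairs are chain ends within r_fusion (geometric
// prefilter), visited in shuffled order; a pair fuses when the nematic angle
// between chain end-to-end axes is within the cutoff and dt*k_fusion >= p.
// Each chain participates in at most one fusion per step. Mixed-direction
// fusions draw the surviving direction uniformly.
void fusion_step_impl(Beads& b, double kfusion, double dt, double rfusion,
                      double cos_cutoff, double t,
                      std::vector<LifecycleEvent>& ev, long& ring_skips);
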