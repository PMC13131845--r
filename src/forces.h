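#pragma once
#include "sim_types.h"

// Bead-chain forces (conservative terms of the mitochondrial equation of
// motion). Each adds into the supplied accumulators; internal pair/triple
// balance makes every term momentum-conserving.
void add_mito_bending(const Beads& b, const std::vector<ChainRun>& runs,
                      double kb_mito, double rm,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz);

void add_mito_springs(const Beads& b, const std::vector<ChainRun>& runs,
                      double ks_mito, double rm,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz);

void add_mito_steric(const Beads& b, double kM, double rm,
                     std::vector<double>& Fx, std::vector<double>& Fy,
                     std::vector<double>& Fz);

// Bead <-> membrane-node WCA pair force; node reaction is the exact negation.
// Returns the number of cap engagements (pairs closer than 0.5*rm, where the
// diverging 1/r^13 magnitude is clamped to its value at 0.5*rm).
long add_wca(const Beads& b,
             const std::vector<double>& nx_, const std::vector<double>& ny_,
             const std::vector<double>& nz_, const CellGrid& grid,
             double phi0, double rm,
             std::vector<double>& Fbx, std::vector<double>& Fby,
             std::vector<double>& Fbz,
             std::vector<double>& Fnx, std::vector<double>& Fny,
             std::vector<double>& Fnz, bool accumulate_node);

// Membrane composite forces.
void add_hinge_bending(const Mesh& m, const std::vector<double>& X,
                       const std::vector<double>& Y, const std::vector<double>& Z,
                       double kb,
                       std::vector<double>& Fx, std::vector<double>& Fy,
                       std::vector<double>& Fz);

double total_mesh_area(const Mesh& m, const std::vector<double>& X,
                       const std::vector<double>& Y, const std::vector<double>& Z);

void add_area_elasticity(const Mesh& m, const std::vector<double>& X,
                         const std::vector<double>& Y, const std::vector<double>& Z,
                         double kAE,
                         std::vector<double>& Fx, std::vector<double>& Fy,
                         std::vector<double>& Fz);

void add_bond_springs(const std::vector<double>& X, const std::vector<double>& Y,
                      const std::vector<double>& Z, const std::vector<int>& b1,
                      const std::vector<int>& b2, const std::vector<double>& rest,
                      double k,
                      std::vector<double>& Fx, std::vector<double>& Fy,
                      std::vector<double>& Fz);
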