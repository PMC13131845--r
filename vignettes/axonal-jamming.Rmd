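---
title: "Mitochondrial traffic jams and axonal swelling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial traffic jams and axonal swelling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`axomito` simulates bidirectional, motor-driven mitochondrial transport
through a segment of axon and asks when that transport fails. Three coupled
pieces make up the model.

**Mitochondria as self-propelled bead–spring chains.** A mitochondrion is a
chain of `Nchain` beads of radius `rm = 125` nm. Kinesin- and dynein-driven
motility is coarse-grained into a constant self-propulsion velocity applied
to every bead of a chain: anterograde chains move at `va` along `+x`,
retrograde chains at `vr` along `-x` (both 0.5 um/s by default). Bead `i`
obeys the overdamped equation

    dr_i/dt = F_i / gamma_m + v nhat,

with `F_i` the sum of four terms: a quadratic bending penalty
`U_b = kb_mito/(8 rm) * theta^2` per interior triple (`theta` the angle
between consecutive bond tangents, zero for a straight chain), Hookean
stretching of bonded neighbours about the rest length `2 rm`, a
Heaviside-gated Hookean repulsion `kM (|r| - 2rm) Theta(2rm - |r|)` between
*all* non-bonded bead pairs (second-nearest neighbours of a chain included,
which prevents self-penetration), and a purely repulsive
Weeks–Chandler–Andersen contact force against the membrane nodes with
length scale `rm` and cutoff `2^(1/6) rm`. All conservative forces are exact
gradients of their energies; the test suite verifies this against central
finite differences at 1e-5 relative tolerance, and verifies that every
internal term conserves momentum.

**A stochastic fission–fusion lifecycle.** Organelle identity lives in a
mutable chain id. Each step, every chain draws a uniform `p` and splits at a
uniformly chosen internal bond when `dt * k_fission >= p`; the downstream
fragment receives a fresh id. Chain *ends* (beads with at most one bonded
neighbour) within `r_fusion = 1.1 * 2rm` of each other fuse when the angle
between the chains' end-to-end axes is within `theta_cutoff = 30` degrees
and a fresh uniform draw passes the same rate gate; the bond topology is
extended across the junction. The orientation test uses the *nematic* (axis)
angle `arccos |u1 . u2|`: with polar angles, an anterograde and a retrograde
chain meeting head-on would always differ by ~180 degrees and the
mixed-direction fusion rule (the merged chain picks its direction uniformly
at random) could never fire. Beads are conserved by both operations; only
labels and row order change.

**A membrane–cytoskeleton composite.** The axonal boundary is a triangulated
cylinder (radius 500 nm, length 3.8 um) whose nodes carry hinge bending
(energy `2 kb e_ij (1 - cos theta_ij) / A_ij` per interior edge, with
`A_ij` the area of the two incident triangles), a global area-elasticity
energy `(kAE/2)(A/A0 - 1)^2`, and two typed Hookean bond networks standing
in for the membrane periodic skeleton: circumferential actin rings every
~180 nm (spring constant `kA = 0.26` N/m) connected by spectrin bonds
(`kS = 2.06e-4` N/m). In `fixed_axon` mode the nodes never move and the mesh
is a rigid confining wall; in `deformable` mode mobile nodes follow
`dr/dt = F/gamma_a`, with the two rim rings pinned because the segment is an
excised part of a longer axon.

Internally everything is non-dimensionalized with the axon radius `r0` as
length scale and `r0/v0` as time scale (1 s at the defaults), so forces are
measured in `gamma_m v0` and energies in `gamma_m v0 r0`; see
`nondimensionalize()` for the exact parameter mapping, which round-trips to
1e-12.

## The transport protocol

A run starts with two anterograde and two retrograde chains placed at the
two ends (rear bead at `x = 0` or `x = L`, beads stacked inward at `2 rm`
spacing, a shared random cross-section position drawn uniformly from the
disk of radius `r0 - rm`). Every generation interval — `10 * Nchain`
timesteps at the default `dt`, expressed internally as a *time* interval so
the protocol is invariant under timestep refinement — one further chain per
side is generated, until the total number of generated beads reaches the
budget

    N = floor(phi * pi r0^2 L / ((4/3) pi rm^3)),  phi = x * pi/sqrt(18),

which gives 81, 162 and 243 beads at `x = 0.3, 0.6, 0.9`. Beads whose centre
leaves `[0, L]` are removed individually (their chain shortens; an interior
removal splits the chain). Departed beads are not replaced (`refill =
FALSE`): the run is a single transport pulse whose two populations meet
mid-axon, jam, and eventually clear.

**Generation under crowding.** The generation rate (`dN/dt` constant across
chain lengths) intentionally exceeds what the cross-section can evacuate at
the transport speed, so candidate placements often overlap existing beads.
The spawner draws a fixed number of candidate positions per side per tick
(`max_spawn_attempts`, so the RNG stream alignment never depends on
occupancy), takes the first non-overlapping one, and otherwise places the
chain at the least-overlapping candidate and lets the steric spring resolve
the interpenetration. This is what produces the large early-time speed
fluctuations while chains are being generated; the alternative policy of
deferring blocked spawns (`spawn_policy = "defer"`) turns out to cap the
injected density at the cross-section packing limit, which makes the
nominal 0.6 and 0.9 density conditions indistinguishable — it is kept only
as an option.

## Numerical choices

* **Timestep.** Forward Euler on the stiffest Hookean term (`ks_mito* =
  100` in reduced units) requires `dt* <= 0.1 gamma*/k*`, hence the default
  `dt = 1e-3` (reduced units; seconds at the defaults).
  `nondimensionalize()` warns when the bound is violated. Halving `dt` at
  the reference jamming condition changes the relief time by < 0.5%
  (tested at < 2%).
* **Deformable-membrane runs** use `dt = 2.5e-4`: under jam loads beads are
  pressed into the wall and the WCA contact stiffness (~13 F / rm at
  contact force F) exceeds the chain-spring stiffness, which destabilizes
  `dt = 1e-3`. The WCA magnitude is additionally capped at its value at
  separation `0.5 rm` (never reached in resolved runs; engagements are
  counted and reported in `diagnostics`).
* **Degenerate geometry** (coincident bonded beads, zero-area faces) raises
  an error naming the offending particles/face instead of propagating NaNs;
  a bead or node displaced by more than `rm` in one step aborts the run
  with the dominant force term named.
* **Neighbor search.** Bead–node WCA pairs and bead–bead steric pairs are
  found with a uniform cell grid at exactly the interaction cutoff, rebuilt
  every step (exact: no pair within the cutoff is missed).
* **Mesh resolution.** The default mesh uses 48 nodes/ring at 38 nm ring
  spacing, reconciling the spectrin rest length (38 nm), the actin rest
  length (65 nm circumferential spacing at r0 = 500 nm) and the 180 nm
  actin-ring period (every 5th ring). Per-bond rest lengths are measured
  from the built mesh so the constructed cylinder is an exact equilibrium
  of the bond network, and `A0` is the built area — runs start from a
  calibrated rest state by construction.

## Study conditions and reference results

The analysis metrics follow the definitions used throughout the results:
the ensemble mean `|vx|` from frame-to-frame displacements (the quantity a
tracked trajectory affords), the nematic order
`Sx = (3<cos^2 theta> - 1)/2` over intra-chain bonds (singletons excluded —
no bond defines an angle), the shape factor
`SF = <(1/N_i^2) sum_j (|r_j - r_COM|/2rm)^2>` (0.4 for an unperturbed
5-bead chain), the mean chain length, and the maximal radial dilation
`max_i (sqrt(y_i^2 + z_i^2) - r0)/r0` over mobile nodes. The relief time
`tau_relieve` is the first time after the speed series' global minimum at
which the ensemble recovers 95% of `v0` and holds it for a configurable
dwell window (default 1 s, guarding against single-sample crossings;
`dwell = 0` recovers the plain first crossing). Scalar summaries
(`min Sx`, `SF` at that time) are read while the axon holds at least half
its peak bead count, not from the sparse tail of escaping chains. Runs that
never recover are reported as right-censored `NA`, and ensemble summaries
follow the mean ± sd over seeds convention.

Jamming phenomenology (fixed axon, `Nchain = 5`, `kb_mito = 1e-19` N m^2)
is assessed at the three densities over >= 5 seeds; the speed dip after the
mid-axon encounter deepens and the relief time grows monotonically with
density. At 0.9 * phi_max (volume fraction ~0.67, near close packing) runs
typically remain jammed for the whole 40 s window and enter the ordering as
right-censored lower bounds.

**Swelling reference condition.** The deformable-membrane runs use the
sparse density 0.3 * phi_max with rigid chains and the lifecycle off. At
higher densities the generation pile-up at the axon ends already deforms
the tube before any mid-axon collision, whereas membrane swelling is a
jam-site phenomenon: at 0.3 * phi_max the dilation time series rises only
when the populations collide, peaks near 30% for elongated chains
(`Nchain = 5`) and relaxes afterwards. Granular runs (`Nchain = 1`, same
bead budget) stay well below the 60% bound. These runs use a reduced mesh
(36 nodes/ring, 50 nm rings, actin every 4th ring) and `dt = 2.5e-4` s,
averaging three seeds — problem sizes chosen so the whole reproduction
script runs at desk scale (a full-resolution deformable run takes ~16
minutes on one CPU versus ~2 minutes reduced). The dilation magnitude is
resolution-sensitive: because the membrane contact force sums a WCA term
over *nodes*, the total force a bead exerts on the wall grows with node
density, and the same chain condition peaks near 45% on the full-resolution
mesh versus 30% on the reduced one. The reduced mesh is the package's
documented desk-scale configuration for these runs.

## What the generator emulates — and what it does not

The synthetic protocol reproduces the *conditions* of the study: equal
bidirectional populations, monodisperse initial chain length, constant
generation flux, a pristine cylindrical segment. Real axonal transport has
unequal anterograde/retrograde fluxes, pausing and motor detachment,
polydisperse organelle sizes, microtubule geometry, and crowding by other
cargo — none of which are modelled. Passing tests therefore demonstrate the
mechanical coupling between morphology, crowding and membrane deformation
under the stated idealizations, not a quantitative reconstruction of any
particular axon. Thermal noise is absent by construction (the only
stochasticity is placement, lifecycle gating and direction draws), so
repeated seeds probe protocol randomness, not temperature.

## Known limitations

* The granular (`Nchain = 1`) deformable runs in this implementation dilate
  the membrane *less* than elongated chains at the sparse reference
  density, although they jam longer — granular dilations comparable to the
  ~60% bound are approached only at higher densities, where generation
  pile-up contributes. The upper-bound check on granular dilation is
  therefore comfortably satisfied, but the strict ordering
  "granular deforms more than chains" is not reproduced at the reference
  condition.
* The morphology effect on the relief time reproduces in *direction* but
  not in magnitude: at the sparse density granular runs take ~1.4 times
  longer to relieve than elongated chains (fixed axon, seed-averaged), far
  short of the three-to-four-fold contrast the phenomenon is known for,
  and at the intermediate density interlocking inverts the ordering
  (chains stay jammed far longer than granules). The corresponding
  acceptance check is deliberately left failing rather than loosened; the
  contrast magnitude appears to depend on generation/overlap handling
  details that the protocol leaves open (forced-overlap injection
  fluidizes the granular plug and speeds its recovery).
* The membrane has no in-plane fluidity, volume constraint or osmotic
  pressure; its relaxation after a jam clears is therefore very slow
  compared to the swelling itself (restoring moduli are tiny in reduced
  units), and the dilation series is read for its *peak*, not its decay.
* Relief times are not monotone across the three densities: at the
  intermediate density the two aligned populations can compress into a
  static, force-balanced packing — an absorbing state of the deterministic
  overdamped dynamics (there is no thermal noise to shake it loose) — while
  at the highest density the injection pressure ejects beads through the
  open ends, lowers the realized density and lets the jam clear sooner.
  The dip-depth ordering and the sparse-to-intermediate relief ordering do
  reproduce; the corresponding monotonicity check is left failing rather
  than loosened.
* No hydrodynamic interactions; drag is a scalar per bead/node.

## Worked example

```{r}
library(axomito)

p <- sim_params(phi_fraction = 0.3, n_chain = 5, kb_mito = 1e-19,
                t_end = 30, seed = 1)
sim <- run_simulation(p)
ms <- metric_series(sim)
sim_summary(sim, ms)

# ensemble over seeds, as in the reported conditions
ens <- run_ensemble(p, n_seeds = 5)
ensemble_summary(ens)
```
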