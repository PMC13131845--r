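#' Maximum filling fraction of close-packed spheres
#'
#' `pi/sqrt(18) ~ 0.7405`, the hexagonal close-packing bound used to convert
#' a relative mitochondrial density into a bead count.
#' @export
phi_max <- pi / sqrt(18)

#' Bead budget for a target mitochondrial density
#'
#' Number of mitochondrial beads corresponding to a volume fraction
#' `phi_fraction * phi_max` of the cylindrical axon, i.e.
#' `floor(phi_fraction * phi_max * pi r0^2 L / ((4/3) pi rm^3))`.
#' With the default geometry (r0 = 0.5 um, L = 3.8 um, rm = 0.125 um) the
#' budgets at `phi_fraction` 0.3, 0.6 and 0.9 are 81, 162 and 243 beads.
#'
#' @param phi_fraction density as a fraction of `phi_max`, in (0, 1].
#' @param r0_a axon radius (um).
#' @param L axon length (um).
#' @param rm mitochondrial bead radius (um).
#' @return integer bead count.
#' @export
bead_budget <- function(phi_fraction, r0_a = 0.5, L = 3.8, rm = 0.125) {
  if (r0_a <= 0 || L <= 0 || rm <= 0)
    stop("bead_budget: geometry parameters must be positive")
  if (any(phi_fraction < 0) || any(phi_fraction > 1))
    stop("bead_budget: phi_fraction must lie in [0, 1]")
  axon_volume <- pi * r0_a^2 * L
  bead_volume <- (4 / 3) * pi * rm^3
  as.integer(floor(phi_fraction * phi_max * axon_volume / bead_volume))
}

#' Model parameters
#'
#' Collects every physical and numerical parameter of the model with the
#' published reference values as defaults. Geometric and kinematic fields are
#' in micrometres and seconds; mechanical moduli keep their laboratory units
#' (N/m, J, N m^2, kg/s) and are converted by [nondimensionalize()].
#'
#' @param r0_a initial axon radius (um).
#' @param L axon length (um).
#' @param rm mitochondrial bead radius (um); bead diameter is `2*rm`.
#' @param l0 spectrin (inter-ring lattice) rest length (um).
#' @param la actin rest length (um).
#' @param actin_period axial spacing of actin rings (um).
#' @param v0 reference mitochondrial speed (um/s), sets the time scale.
#' @param va,vr anterograde / retrograde self-propulsion speeds (um/s).
#' @param phi_fraction mitochondrial density as a fraction of [phi_max].
#' @param n_chain beads per generated mitochondrion (aspect ratio).
#' @param gamma_m,gamma_a drag coefficients of beads and membrane nodes (kg/s).
#' @param kb_mito chain bending rigidity (N m^2); the studied range is
#'   1e-21 to 1e-19, default is the rigid end.
#' @param ks_mito chain spring constant (N/m).
#' @param kM bead-bead steric spring constant (N/m).
#' @param phi0 bead-membrane WCA interaction strength (J).
#' @param kb_membrane membrane bending rigidity (J).
#' @param kAE membrane area elasticity modulus (J).
#' @param kS,kA spectrin and actin spring coefficients (N/m).
#' @param k_fission,k_fusion lifecycle rate constants (1/s); the studied
#'   range is 0.01 to 100, default 0 (lifecycle off).
#' @param r_fusion maximum end-bead separation for fusion (um).
#' @param theta_cutoff maximum nematic angle between chain axes for fusion
#'   (degrees).
#' @param dt timestep (s). The default satisfies the forward-Euler stability
#'   bound `dt* <= 0.1 * gamma* / k*max` for the stiffest spring
#'   (`ks_mito* = 100` in reduced units).
#' @param t_end simulated time (s).
#' @param output_interval interval between recorded frames (s).
#' @param mesh_output_stride record membrane node frames every this many
#'   bead frames.
#' @param generation_interval time between generation events (s); the default
#'   `10 * n_chain * 1e-3 * r0_a/v0` reproduces the every-`10*n_chain`-steps
#'   cadence at the default timestep while staying invariant under dt
#'   refinement.
#' @param initial_pairs chains generated per side at t = 0.
#' @param max_spawn_attempts random cross-section placements tried per
#'   generation before the spawn policy decides.
#' @param spawn_policy what to do when every candidate placement overlaps an
#'   existing bead: `"force"` (default) places the chain at the
#'   least-overlapping candidate and lets the steric term resolve the
#'   overlap, keeping the generation rate constant as the protocol requires;
#'   `"defer"` postpones the spawn to the next cadence tick (which caps the
#'   injection rate at the cross-section packing limit and starves dense
#'   runs).
#' @param refill if `FALSE` (default) the bead budget counts all beads ever
#'   generated; if `TRUE` departed beads are replaced to hold density.
#' @param nodes_per_ring,ring_spacing membrane mesh resolution; defaults give
#'   circumferential node spacing ~ `la` and axial spacing `l0`.
#' @param mode `"fixed_axon"` (membrane nodes never move) or `"deformable"`.
#' @param seed RNG seed; one stream drives placement, fission, fusion and
#'   direction draws.
#' @return an object of class `sim_params`.
#' @seealso [run_simulation()], [nondimensionalize()]
#' @export
sim_params <- function(r0_a = 0.5, L = 3.8, rm = 0.125,
                       l0 = 0.038, la = 0.065, actin_period = 0.18,
                       v0 = 0.5, va = 0.5, vr = 0.5,
                       phi_fraction = 0.3, n_chain = 5L,
                       gamma_m = 1, gamma_a = 1,
                       kb_mito = 1e-19, ks_mito = 100, kM = 40,
                       phi0 = 5e-15,
                       kb_membrane = 5e-19, kAE = 1e-15,
                       kS = 2.06e-4, kA = 0.26,
                       k_fission = 0, k_fusion = 0,
                       r_fusion = 1.1 * 2 * rm, theta_cutoff = 30,
                       dt = 1e-3, t_end = 30, output_interval = 0.05,
                       mesh_output_stride = 5L,
                       generation_interval = NULL,
                       initial_pairs = 2L, max_spawn_attempts = 20L,
                       spawn_policy = c("force", "defer"),
                       refill = FALSE,
                       nodes_per_ring = 48L, ring_spacing = 0.038,
                       mode = c("fixed_axon", "deformable"),
                       seed = 1L) {
  mode <- match.arg(mode)
  spawn_policy <- match.arg(spawn_policy)
  if (r0_a <= 0 || L <= 0 || rm <= 0 || v0 <= 0)
    stop("sim_params: geometry and speed scales must be positive")
  if (dt <= 0) stop("sim_params: dt must be positive")
  if (t_end <= 0) stop("sim_params: t_end must be positive")
  if (phi_fraction <= 0 || phi_fraction > 1)
    stop("sim_params: phi_fraction must lie in (0, 1]")
  if (n_chain < 1) stop("sim_params: n_chain must be >= 1")
  if (k_fission < 0 || k_fusion < 0)
    stop("sim_params: lifecycle rates must be non-negative")
  if (r_fusion <= 0) stop("sim_params: r_fusion must be positive")
  if (theta_cutoff <= 0 || theta_cutoff > 180)
    stop("sim_params: theta_cutoff must lie in (0, 180]")
  stopifnot(all(c(gamma_m, gamma_a, ks_mito, kM, phi0, kb_membrane, kAE,
                  kS, kA, kb_mito) > 0))
  t0 <- r0_a / v0
  if (is.null(generation_interval))
    generation_interval <- 10 * n_chain * 1e-3 * t0
  p <- list(r0_a = r0_a, L = L, rm = rm, l0 = l0, la = la,
            actin_period = actin_period,
            v0 = v0, va = va, vr = vr,
            phi_fraction = phi_fraction, n_chain = as.integer(n_chain),
            gamma_m = gamma_m, gamma_a = gamma_a,
            kb_mito = kb_mito, ks_mito = ks_mito, kM = kM, phi0 = phi0,
            kb_membrane = kb_membrane, kAE = kAE, kS = kS, kA = kA,
            k_fission = k_fission, k_fusion = k_fusion,
            r_fusion = r_fusion, theta_cutoff = theta_cutoff,
            dt = dt, t_end = t_end, output_interval = output_interval,
            mesh_output_stride = as.integer(mesh_output_stride),
            generation_interval = generation_interval,
            initial_pairs = as.integer(initial_pairs),
            max_spawn_attempts = as.integer(max_spawn_attempts),
            spawn_policy = spawn_policy,
            refill = isTRUE(refill),
            nodes_per_ring = as.integer(nodes_per_ring),
            ring_spacing = ring_spacing,
            mode = mode, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Axonal mitochondrial transport parameters\n")
  cat(sprintf("  axon: r0 = %g um, L = %g um, mesh %d nodes/ring @ %g um\n",
              x$r0_a, x$L, x$nodes_per_ring, x$ring_spacing))
  cat(sprintf("  mitochondria: rm = %g um, Nchain = %d, phi = %.2f*phi_max (%d beads)\n",
              x$rm, x$n_chain, x$phi_fraction,
              bead_budget(x$phi_fraction, x$r0_a, x$L, x$rm)))
  cat(sprintf("  propulsion: va = %g, vr = %g um/s; kb_mito = %g N m^2\n",
              x$va, x$vr, x$kb_mito))
  cat(sprintf("  lifecycle: k_fission = %g, k_fusion = %g /s\n",
              x$k_fission, x$k_fusion))
  cat(sprintf("  numerics: dt = %g s, t_end = %g s, mode = %s, seed = %d\n",
              x$dt, x$t_end, x$mode, x$seed))
  invisible(x)
}

#' Reduce parameters to dimensionless internal units
#'
#' Lengths are scaled by the axon radius `r0_a` and times by `r0_a/v0`, so
#' forces are measured in units of `gamma_m*v0` and energies in
#' `gamma_m*v0*r0_a`. Spring constants (N/m) map to
#' `k* = k * r0_a / (gamma_m v0)`, energies (J) to `E* = E/(gamma_m v0 r0_a)`,
#' chain bending rigidity (N m^2) to `kb* = kb/(gamma_m v0 r0_a^2)` and rates
#' to `k* = k * r0_a/v0`. [redimensionalize()] inverts the map exactly.
#'
#' @param params a [sim_params()] object.
#' @return a list of dimensionless parameters (class `sim_params_nd`) with the
#'   scale factors attached.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  r0_m <- p$r0_a * 1e-6            # m
  v0_m <- p$v0 * 1e-6              # m/s
  t0 <- p$r0_a / p$v0              # s
  F0 <- p$gamma_m * v0_m           # N
  E0 <- F0 * r0_m                  # J
  k_scale <- r0_m / F0             # (N/m) -> dimensionless
  dtn <- p$dt / t0
  k_stiffest <- max(p$ks_mito, p$kM) * k_scale
  dt_bound <- 0.1 * 1 / k_stiffest
  if (dtn > dt_bound)
    warning(sprintf(paste0("dt* = %.3g exceeds the forward-Euler stability ",
                           "bound 0.1*gamma*/k*max = %.3g"), dtn, dt_bound))
  nd <- list(
    L = p$L / p$r0_a, rm = p$rm / p$r0_a,
    l0 = p$l0 / p$r0_a, la = p$la / p$r0_a,
    actin_period = p$actin_period / p$r0_a,
    ring_spacing = p$ring_spacing / p$r0_a,
    r_spawn = (p$r0_a - p$rm) / p$r0_a,
    va = p$va / p$v0, vr = p$vr / p$v0,
    gamma_m = 1, gamma_a = p$gamma_a / p$gamma_m,
    kb_mito = p$kb_mito / (F0 * r0_m^2),
    ks_mito = p$ks_mito * k_scale,
    kM = p$kM * k_scale,
    phi0 = p$phi0 / E0,
    kb_mem = p$kb_membrane / E0,
    kAE = p$kAE / E0,
    kS = p$kS * k_scale,
    kA = p$kA * k_scale,
    kfission = p$k_fission * t0,
    kfusion = p$k_fusion * t0,
    rfusion = p$r_fusion / p$r0_a,
    cos_cutoff = cos(p$theta_cutoff * pi / 180),
    dt = dtn,
    t_end = p$t_end / t0,
    output_interval = p$output_interval / t0,
    generation_interval = p$generation_interval / t0,
    dt_bound = dt_bound)
  attr(nd, "scales") <- list(length_um = p$r0_a, time_s = t0,
                             speed_um_s = p$v0, force_N = F0, energy_J = E0)
  attr(nd, "params") <- params
  class(nd) <- "sim_params_nd"
  nd
}

#' Recover physical parameters from the dimensionless set
#'
#' Exact inverse of [nondimensionalize()]; used to verify the scaling
#' round-trips and to express internal quantities in laboratory units.
#'
#' @param nd a `sim_params_nd` object.
#' @return the original [sim_params()] object reconstructed from the
#'   dimensionless values and scale factors.
#' @export
redimensionalize <- function(nd) {
  stopifnot(inherits(nd, "sim_params_nd"))
  sc <- attr(nd, "scales")
  p0 <- attr(nd, "params")
  r0 <- sc$length_um
  t0 <- sc$time_s
  F0 <- sc$force_N
  E0 <- sc$energy_J
  r0_m <- r0 * 1e-6
  k_unscale <- F0 / r0_m
  out <- sim_params(
    r0_a = r0, L = nd$L * r0, rm = nd$rm * r0,
    l0 = nd$l0 * r0, la = nd$la * r0, actin_period = nd$actin_period * r0,
    v0 = sc$speed_um_s, va = nd$va * sc$speed_um_s, vr = nd$vr * sc$speed_um_s,
    phi_fraction = p0$phi_fraction, n_chain = p0$n_chain,
    gamma_m = p0$gamma_m, gamma_a = nd$gamma_a * p0$gamma_m,
    kb_mito = nd$kb_mito * F0 * r0_m^2,
    ks_mito = nd$ks_mito * k_unscale, kM = nd$kM * k_unscale,
    phi0 = nd$phi0 * E0, kb_membrane = nd$kb_mem * E0, kAE = nd$kAE * E0,
    kS = nd$kS * k_unscale, kA = nd$kA * k_unscale,
    k_fission = nd$kfission / t0, k_fusion = nd$kfusion / t0,
    r_fusion = nd$rfusion * r0, theta_cutoff = acos(nd$cos_cutoff) * 180 / pi,
    dt = nd$dt * t0, t_end = nd$t_end * t0,
    output_interval = nd$output_interval * t0,
    mesh_output_stride = p0$mesh_output_stride,
    generation_interval = nd$generation_interval * t0,
    initial_pairs = p0$initial_pairs,
    max_spawn_attempts = p0$max_spawn_attempts,
    spawn_policy = p0$spawn_policy,
    refill = p0$refill,
    nodes_per_ring = p0$nodes_per_ring, ring_spacing = nd$ring_spacing * r0,
    mode = p0$mode, seed = p0$seed)
  out
}
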