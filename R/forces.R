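# Force wrappers. These operate in whatever consistent unit system the
# caller supplies (the engine uses reduced units internally); forces come
# back as n x 3 matrices aligned with the input rows.

#' Chain bending forces
#'
#' Restoring forces of the quadratic bending energy `U = kb/(8 rm) * theta^2`
#' summed over interior bead triples, where `theta` is the angle between
#' consecutive bond tangents (0 for a collinear triple). Forces are the exact
#' energy gradient, so each triple's three forces sum to zero. Chains shorter
#' than 3 beads contribute nothing.
#'
#' @param beads a [bead_table()].
#' @param kb_mito bending rigidity (energy x length, e.g. N m^2).
#' @param rm bead radius.
#' @return n x 3 force matrix.
#' @export
mito_bending_forces <- function(beads, kb_mito, rm = attr(beads, "rm")) {
  validate_bead_table(beads, rm = NULL)
  cpp_mito_bending(bead_pos(beads), beads$particle_id, beads$chain_id,
                   dir_to_int(beads$direction), kb_mito, rm)
}

#' Chain spring (stretching) forces
#'
#' Pairwise Hookean forces between bonded neighbours with rest length `2*rm`:
#' attractive when a bond is stretched, repulsive when compressed.
#'
#' @inheritParams mito_bending_forces
#' @param ks_mito spring constant (force/length).
#' @return n x 3 force matrix.
#' @export
mito_spring_forces <- function(beads, ks_mito, rm = attr(beads, "rm")) {
  validate_bead_table(beads, rm = NULL)
  cpp_mito_springs(bead_pos(beads), beads$particle_id, beads$chain_id,
                   dir_to_int(beads$direction), ks_mito, rm)
}

#' Steric (volume-exclusion) forces
#'
#' Heaviside-gated Hookean repulsion between every bead pair that is not a
#' bonded intra-chain neighbour pair (second-nearest neighbours of the same
#' chain do interact): nonzero only when centres overlap (`|r| < 2*rm`),
#' equal and opposite on the pair.
#'
#' @inheritParams mito_bending_forces
#' @param kM steric spring constant (force/length).
#' @return n x 3 force matrix.
#' @export
mito_steric_forces <- function(beads, kM, rm = attr(beads, "rm")) {
  validate_bead_table(beads, rm = NULL)
  cpp_mito_steric(bead_pos(beads), beads$particle_id, beads$chain_id,
                  dir_to_int(beads$direction), kM, rm)
}

#' Bead-membrane WCA contact forces
#'
#' Purely repulsive Weeks-Chandler-Andersen force between each bead and each
#' membrane node closer than the cutoff `2^(1/6)*rm` (length scale `rm`);
#' the node receives exactly the negated bead force. The diverging small-
#' separation magnitude is capped at its value at `0.5*rm`; a warning reports
#' how many pairs hit the cap.
#'
#' @param beads a [bead_table()] (or n x 3 position matrix).
#' @param nodes m x 3 membrane node positions.
#' @param phi0 interaction strength (energy).
#' @param rm bead radius.
#' @return list with `bead` (n x 3) and `node` (m x 3) force matrices.
#' @export
wca_membrane_forces <- function(beads, nodes, phi0, rm = attr(beads, "rm")) {
  pos <- if (is.matrix(beads)) beads else bead_pos(beads)
  out <- cpp_wca(pos, as.matrix(nodes), phi0, rm)
  if (out$cap_hits > 0)
    warning(sprintf("WCA force cap engaged for %d bead-node pair(s) closer than 0.5*rm",
                    as.integer(out$cap_hits)))
  out[c("bead", "node")]
}

#' Advance beads one forward-Euler step
#'
#' Overdamped update `r(t+dt) = r(t) + dt*(F/gamma_m + v*nhat)` with `nhat = +x` and
#' speed `va` for anterograde chains, `-x` and `vr` for retrograde chains;
#' the propulsion term applies to every bead of a chain.
#'
#' @param beads a [bead_table()].
#' @param forces n x 3 matrix of total forces.
#' @param dt timestep (> 0).
#' @param gamma_m bead drag coefficient.
#' @param va,vr propulsion speeds.
#' @return the updated [bead_table()].
#' @export
advance_beads <- function(beads, forces, dt, gamma_m = 1, va = 0.5, vr = 0.5) {
  if (dt <= 0) stop("advance_beads: dt must be positive")
  forces <- as.matrix(forces)
  vprop <- ifelse(beads$direction == "anterograde", va, -vr)
  beads$x <- beads$x + dt * (forces[, 1] / gamma_m + vprop)
  beads$y <- beads$y + dt * forces[, 2] / gamma_m
  beads$z <- beads$z + dt * forces[, 3] / gamma_m
  beads
}

#' Membrane bending forces
#'
#' Exact gradient of the hinge bending energy
#' `E = 2*kb*(e_ij/A_ij)*(1 - cos(theta_ij))` summed over interior edges,
#' where `e_ij` is the hinge edge length, `A_ij` the summed area of the two
#' incident triangles and `theta_ij` the dihedral angle (0 for coplanar
#' faces). The four per-hinge vertex forces sum to zero.
#'
#' @param mesh a `membrane_mesh`.
#' @param kb bending rigidity (energy).
#' @param nodes optional node positions overriding `mesh$nodes`.
#' @return n x 3 force matrix.
#' @export
membrane_bending_forces <- function(mesh, kb, nodes = mesh$nodes) {
  cpp_membrane_bending(mesh_cpp_list(mesh), as.matrix(nodes), kb)
}

#' Global area-elasticity forces
#'
#' Restoring force `-(kAE/A0)*(A/A0 - 1) * sum_f grad_i A_f`, the exact
#' gradient of `E = (kAE/2)*(A/A0 - 1)^2`, which drives the total triangle
#' area `A` back to the reference `A0`.
#'
#' @inheritParams membrane_bending_forces
#' @param kAE area elasticity modulus (energy).
#' @return n x 3 force matrix.
#' @export
area_elasticity_forces <- function(mesh, kAE, nodes = mesh$nodes) {
  cpp_area_forces(mesh_cpp_list(mesh), as.matrix(nodes), kAE)
}

#' Total triangulated surface area
#'
#' @inheritParams membrane_bending_forces
#' @return total area in the square of the node position unit.
#' @export
mesh_area <- function(mesh, nodes = mesh$nodes) {
  cpp_mesh_area(mesh_cpp_list(mesh), as.matrix(nodes))
}

#' Cytoskeletal (spectrin + actin) spring forces
#'
#' Hookean forces of the typed bond networks with their per-bond rest
#' lengths: attractive when stretched, repulsive when compressed, equal and
#' opposite on each bond.
#'
#' @inheritParams membrane_bending_forces
#' @param kS,kA spectrin and actin spring coefficients (force/length).
#' @return n x 3 force matrix.
#' @export
cytoskeleton_forces <- function(mesh, kS, kA, nodes = mesh$nodes) {
  nodes <- as.matrix(nodes)
  f <- matrix(0, nrow(nodes), 3)
  if (nrow(mesh$spectrin_bonds))
    f <- f + cpp_bond_forces(nodes, mesh$spectrin_bonds, mesh$spectrin_rest, kS)
  if (nrow(mesh$actin_bonds))
    f <- f + cpp_bond_forces(nodes, mesh$actin_bonds, mesh$actin_rest, kA)
  f
}

#' Advance membrane nodes one forward-Euler step
#'
#' Overdamped update `r(t+dt) = r(t) + dt*F/gamma_a` applied to mobile nodes only.
#' In fixed-axon mode (`mode = "fixed_axon"`) no node moves regardless of the
#' forces; pinned rim nodes never move in either mode.
#'
#' @param mesh a `membrane_mesh`.
#' @param forces n x 3 matrix of total node forces.
#' @param dt timestep (> 0).
#' @param gamma_a node drag coefficient.
#' @param mode `"deformable"` or `"fixed_axon"`.
#' @return the mesh with updated `nodes`.
#' @export
advance_membrane <- function(mesh, forces, dt, gamma_a = 1,
                             mode = c("deformable", "fixed_axon")) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("advance_membrane: dt must be positive")
  if (mode == "fixed_axon") return(mesh)
  forces <- as.matrix(forces)
  mob <- mesh$mobile
  mesh$nodes[mob, ] <- mesh$nodes[mob, ] + dt * forces[mob, , drop = FALSE] / gamma_a
  mesh
}

# internal: fields the C++ kernels need, in their expected types
mesh_cpp_list <- function(mesh) {
  list(nodes = as.matrix(mesh$nodes),
       faces = matrix(as.integer(mesh$faces), ncol = 3),
       hinges = matrix(as.integer(mesh$hinges), ncol = 4),
       spectrin_bonds = matrix(as.integer(mesh$spectrin_bonds), ncol = 2),
       spectrin_rest = as.numeric(mesh$spectrin_rest),
       actin_bonds = matrix(as.integer(mesh$actin_bonds), ncol = 2),
       actin_rest = as.numeric(mesh$actin_rest),
       mobile = as.logical(mesh$mobile),
       A0 = mesh$A0)
}
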