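# Deterministic generators of small test inputs. All fixtures are pure
# functions of their arguments (and seed where one applies).

#' Straight bead-spring chain at rest spacing
#'
#' @param n_beads chain length.
#' @param rm bead radius (um); bonds are at the rest length `2*rm`.
#' @param direction transport direction label.
#' @param origin position of the first (rear) bead.
#' @param axis chain axis (normalized internally).
#' @param chain_id,particle_id_start id bookkeeping.
#' @return a [bead_table()].
#' @export
make_straight_chain <- function(n_beads, rm = 0.125,
                                direction = "anterograde",
                                origin = c(0, 0, 0), axis = c(1, 0, 0),
                                chain_id = 1L, particle_id_start = 1L) {
  axis <- axis / sqrt(sum(axis^2))
  s <- seq(0, by = 2 * rm, length.out = n_beads)
  pos <- cbind(origin[1] + s * axis[1], origin[2] + s * axis[2],
               origin[3] + s * axis[3])
  bead_table(pos, chain_id = chain_id, direction = direction,
             particle_id = seq(particle_id_start, length.out = n_beads),
             rm = rm)
}

#' Chain folded at its midpoint
#'
#' A planar chain with all bonds at rest length and a single kink of the
#' given angle at the central bead; `angle = 0` recovers a straight chain.
#' Useful as a constant-bond-length deformation for shape-factor checks.
#'
#' @param n_beads odd chain length.
#' @param angle fold angle at the midpoint (degrees).
#' @inheritParams make_straight_chain
#' @return a [bead_table()].
#' @export
make_folded_chain <- function(n_beads, angle, rm = 0.125,
                              direction = "anterograde", chain_id = 1L) {
  if (n_beads %% 2 == 0) stop("make_folded_chain: n_beads must be odd")
  mid <- (n_beads + 1) / 2
  a <- angle * pi / 180
  pos <- matrix(0, n_beads, 3)
  for (i in seq_len(n_beads)) {
    if (i <= mid) {
      pos[i, ] <- c((i - 1) * 2 * rm, 0, 0)
    } else {
      k <- i - mid
      pos[i, ] <- pos[mid, ] + k * 2 * rm * c(cos(a), sin(a), 0)
    }
  }
  bead_table(pos, chain_id = chain_id, direction = direction, rm = rm)
}

#' Ensemble of 2-bead chains with isotropic bond orientations
#'
#' Bond directions are drawn uniformly on the sphere, so the expected nematic
#' order along any axis is 0 (`<cos^2 theta> = 1/3`).
#'
#' @param n_bonds number of chains (one bond each).
#' @param rm bead radius (um).
#' @param seed RNG seed; same seed, same fixture.
#' @return a [bead_table()].
#' @export
make_isotropic_bonds <- function(n_bonds, rm = 0.125, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- runif(n_bonds, -1, 1)
  phi <- runif(n_bonds, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  d <- cbind(s * cos(phi), s * sin(phi), u)
  origins <- cbind(runif(n_bonds, 0, 10), runif(n_bonds, -1, 1),
                   runif(n_bonds, -1, 1))
  pos <- matrix(0, 2 * n_bonds, 3)
  pos[seq(1, 2 * n_bonds, 2), ] <- origins
  pos[seq(2, 2 * n_bonds, 2), ] <- origins + 2 * rm * d
  bead_table(pos, chain_id = rep(seq_len(n_bonds), each = 2),
             direction = "anterograde", rm = rm)
}

#' Head-on pair of counter-propagating chains
#'
#' One anterograde and one retrograde straight chain, coaxial (or laterally
#' offset), facing each other with the given head-to-head gap: the minimal
#' collision scenario of the mid-axon encounter between the two populations.
#'
#' @param gap head-to-head separation (um), must be positive.
#' @param n_chain beads per chain.
#' @param rm bead radius (um).
#' @param lateral_offset y-offset of the retrograde chain (um).
#' @param x_head x-position of the anterograde head bead.
#' @return a [bead_table()] with chains 1 (anterograde) and 2 (retrograde).
#' @export
make_head_on_pair <- function(gap, n_chain = 5L, rm = 0.125,
                              lateral_offset = 0, x_head = 0) {
  if (gap <= 0) stop("make_head_on_pair: gap must be positive")
  a <- make_straight_chain(n_chain, rm = rm, direction = "anterograde",
                           origin = c(x_head - (n_chain - 1) * 2 * rm, 0, 0),
                           chain_id = 1L, particle_id_start = 1L)
  r <- make_straight_chain(n_chain, rm = rm, direction = "retrograde",
                           origin = c(x_head + gap + (n_chain - 1) * 2 * rm,
                                      lateral_offset, 0),
                           axis = c(-1, 0, 0),
                           chain_id = 2L,
                           particle_id_start = n_chain + 1L)
  out <- rbind(a, r)
  attr(out, "rm") <- rm
  class(out) <- c("bead_table", "data.frame")
  out
}

#' Small membrane tube for force-oracle tests
#'
#' A tiny triangulated cylinder with the same topology contracts as the full
#' mesh (`rings x nodes_per_ring` nodes, `2*nodes_per_ring*(rings-1)` faces).
#'
#' @param rings number of node rings (>= 2).
#' @param nodes_per_ring nodes per ring (>= 3).
#' @param r0_a tube radius (um).
#' @param length tube length (um).
#' @return a `membrane_mesh` (see [build_cylinder_mesh()]).
#' @export
make_mini_mesh <- function(rings = 4L, nodes_per_ring = 8L, r0_a = 0.5,
                           length = 1) {
  build_cylinder_mesh(r0_a = r0_a, L = length,
                      ring_spacing = length / (rings - 1),
                      nodes_per_ring = nodes_per_ring,
                      actin_period = 2 * length / (rings - 1))
}

#' Synthetic ensemble-speed trace with a jamming dip
#'
#' Piecewise-linear speed series: baseline `v0`, linear drop to `v_min` at
#' `t_min`, linear recovery back to `v0` at `t_rec`. The exact first crossing
#' of `threshold*v0` on the recovery ramp is
#' `t_min + (t_rec - t_min) * (threshold*v0 - v_min)/(v0 - v_min)`.
#'
#' @param v0 baseline speed.
#' @param v_min dip minimum.
#' @param t_min,t_rec dip and recovery times.
#' @param t_end,dt series extent and sample interval.
#' @return a `data.frame` with columns `time` and `speed`.
#' @export
make_speed_trace <- function(v0 = 0.5, v_min = 0.1, t_min = 5, t_rec = 12,
                             t_end = 20, dt = 0.25) {
  time <- seq(0, t_end, by = dt)
  speed <- ifelse(time <= t_min * 0.5, v0,
           ifelse(time <= t_min,
                  v0 + (v_min - v0) * (time - t_min * 0.5) / (t_min * 0.5),
           ifelse(time <= t_rec,
                  v_min + (v0 - v_min) * (time - t_min) / (t_rec - t_min),
                  v0)))
  data.frame(time = time, speed = speed)
}
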