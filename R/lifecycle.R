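# Stochastic lifecycle: rate-gated chain-identity rewrites. Both operations
# conserve beads (only chain_id labels and row order change) and draw from
# R's RNG stream, so event sequences are reproducible under set.seed().

#' One fission step
#'
#' For each chain independently a uniform `p` in `[0,1)` is drawn; the chain
#' splits when `dt * k_fission >= p`. The split occurs at a bond chosen
#' uniformly among the chain's internal bonds, and the downstream fragment
#' receives a fresh chain id (singletons never fission). Particle ids and
#' positions are untouched.
#'
#' @param beads a [bead_table()].
#' @param k_fission fission rate constant (inverse time).
#' @param dt timestep (same time unit).
#' @param time timestamp recorded in the event log.
#' @param next_chain_id first unused chain id; defaults to
#'   `max(chain_id) + 1`.
#' @return list with the updated `beads`, the event log `events`
#'   (`data.frame`: time, type, chain_a = parent, chain_b = new id, x), and
#'   `next_chain_id`.
#' @export
fission_step <- function(beads, k_fission, dt, time = 0,
                         next_chain_id = NULL) {
  validate_bead_table(beads, rm = NULL)
  if (is.null(next_chain_id)) next_chain_id <- max(beads$chain_id) + 1L
  out <- cpp_fission_step(bead_pos(beads), beads$particle_id, beads$chain_id,
                          dir_to_int(beads$direction), k_fission, dt,
                          as.integer(next_chain_id), time)
  list(beads = beads_from_cpp(out, attr(beads, "rm")),
       events = events_df(out$events),
       next_chain_id = out$next_cid)
}

#' One fusion step
#'
#' Candidate pairs are chain end beads (beads with at most one intra-chain
#' neighbour, including singletons) within `r_fusion` of each other, visited
#' in shuffled order; each chain fuses at most once per step. A pair fuses
#' when the nematic angle between the chains' end-to-end axes is within
#' `theta_cutoff` and a fresh uniform `p` satisfies `dt * k_fusion >= p`.
#' The merged chain takes one chain id, the spring-bond topology is extended
#' across the junction, same-direction pairs keep their direction, and
#' mixed-direction pairs draw the surviving direction uniformly. An attempt
#' to fuse the two ends of one chain (ring closure) is skipped and logged.
#'
#' @param beads a [bead_table()].
#' @param k_fusion fusion rate constant (inverse time).
#' @param dt timestep.
#' @param r_fusion maximum end-bead separation (position units).
#' @param theta_cutoff maximum chain-axis angle (degrees).
#' @param time timestamp recorded in the event log.
#' @return list with updated `beads`, `events` (type `"fusion"` rows plus
#'   `"ring_skip"` rows for skipped self-fusions), and the `ring_skips`
#'   count.
#' @export
fusion_step <- function(beads, k_fusion, dt, r_fusion = 0.275,
                        theta_cutoff = 30, time = 0) {
  validate_bead_table(beads, rm = NULL)
  out <- cpp_fusion_step(bead_pos(beads), beads$particle_id, beads$chain_id,
                         dir_to_int(beads$direction), k_fusion, dt, r_fusion,
                         cos(theta_cutoff * pi / 180), time)
  list(beads = beads_from_cpp(out, attr(beads, "rm")),
       events = events_df(out$events),
       ring_skips = out$ring_skips)
}

# internal: C++ event vectors -> tidy data.frame
events_df <- function(ev) {
  type <- c("fission", "fusion", "ring_skip")[ev$type]
  data.frame(time = ev$time, type = type, chain_a = ev$chain_a,
             chain_b = ev$chain_b, x = ev$x, stringsAsFactors = FALSE)
}
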