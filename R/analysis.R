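# Results-section metrics: nematic order, shape factor, relief time, radial
# dilation, chain-length statistics, and the per-frame metric series.

#' Nematic order parameter along the axon axis
#'
#' `Sx = (3<cos^2 theta> - 1)/2` where `theta` is the angle between each
#' intra-chain neighbour separation vector and the x axis, averaged over all
#' bonds of all chains. 1 means all bonds parallel to x, 0 an isotropic bond
#' distribution, -0.5 all bonds perpendicular. Singleton chains carry no
#' bond and contribute nothing; with no bonds at all the value is undefined
#' and `NA` is returned (flagged via `attr(, "n_bonds")`).
#'
#' @param beads a [bead_table()].
#' @return `Sx` in `[-0.5, 1]`, or `NA` if no bond exists.
#' @export
nematic_order_x <- function(beads) {
  n <- nrow(beads)
  if (n < 2) return(structure(NA_real_, n_bonds = 0L))
  same <- beads$chain_id[-1] == beads$chain_id[-n]
  if (!any(same)) return(structure(NA_real_, n_bonds = 0L))
  dx <- diff(beads$x)[same]
  dy <- diff(beads$y)[same]
  dz <- diff(beads$z)[same]
  cos2 <- dx^2 / (dx^2 + dy^2 + dz^2)
  structure((3 * mean(cos2) - 1) / 2, n_bonds = sum(same))
}

#' Per-chain shape factor
#'
#' `SF = (1/Nchains) sum_i (1/Nchain_i^2) sum_j (|r_j - r_COM,i| / 2rm)^2`:
#' the second moment of each chain about its centre of mass in bead-diameter
#' units, weighted by the inverse squared chain length, averaged over chains.
#' Large for elongated chains (0.4 for an unperturbed 5-bead chain), 0 for a
#' single bead; folding a chain at constant bond lengths strictly decreases
#' it.
#'
#' @param beads a [bead_table()].
#' @param rm bead radius (position units).
#' @return mean shape factor over chains.
#' @export
shape_factor <- function(beads, rm = attr(beads, "rm")) {
  if (nrow(beads) == 0) stop("shape_factor: empty bead table")
  per_chain <- function(ix) {
    cx <- beads$x[ix] - mean(beads$x[ix])
    cy <- beads$y[ix] - mean(beads$y[ix])
    cz <- beads$z[ix] - mean(beads$z[ix])
    sum((cx^2 + cy^2 + cz^2) / (2 * rm)^2) / length(ix)^2
  }
  mean(vapply(split(seq_len(nrow(beads)), beads$chain_id), per_chain,
              numeric(1)))
}

#' Mean chain length
#'
#' @param beads a [bead_table()].
#' @return arithmetic mean of beads per chain.
#' @export
mean_chain_length <- function(beads) {
  if (nrow(beads) == 0) stop("mean_chain_length: empty bead table")
  mean(as.numeric(table(beads$chain_id)))
}

#' Maximum radial membrane dilation
#'
#' `max over nodes of (sqrt(y^2 + z^2) - r0)/r0`, i.e. the peak fractional
#' increase of node radial distance over the rest radius; 0 for the
#' unperturbed cylinder.
#'
#' @param nodes n x 3 node positions.
#' @param r0_a rest radius (same units).
#' @param mobile optional logical mask restricting the max to mobile nodes.
#' @return dilation as a fraction of `r0_a`.
#' @export
max_radial_dilation <- function(nodes, r0_a, mobile = NULL) {
  nodes <- as.matrix(nodes)
  r <- sqrt(nodes[, 2]^2 + nodes[, 3]^2)
  if (!is.null(mobile)) r <- r[mobile]
  max((r - r0_a) / r0_a)
}

#' Jamming relief time
#'
#' Time for the ensemble axial speed to recover `threshold` (default 95%) of
#' the self-propulsion speed after its collision-induced global minimum,
#' measured from t = 0. The series must dip below `threshold*v0` (otherwise
#' `NA` flagged `"no_dip"`); the crossing must then hold for `dwell` seconds
#' of samples (guarding against single-sample noise; `dwell = 0` recovers
#' the plain first crossing). If the speed never recovers within the series
#' the value is right-censored (`NA` flagged `"censored"`).
#'
#' @param time sample times (s).
#' @param speed mean |vx| series (same length; NA samples are dropped).
#' @param v0 imposed self-propulsion speed.
#' @param threshold recovery fraction (default 0.95).
#' @param dwell time the recovery must persist (s).
#' @param interpolate if TRUE, linearly interpolate the exact crossing
#'   between the last sub-threshold and the first super-threshold sample;
#'   default FALSE reports the first super-threshold sample time.
#' @return the relief time (s), or flagged `NA` (see `attr(, "reason")`).
#' @export
relief_time <- function(time, speed, v0, threshold = 0.95, dwell = 1,
                        interpolate = FALSE) {
  keep <- is.finite(speed)
  time <- time[keep]
  speed <- speed[keep]
  if (length(speed) == 0) return(structure(NA_real_, reason = "empty"))
  thr <- threshold * v0
  imin <- which.min(speed)
  if (speed[imin] >= thr) return(structure(NA_real_, reason = "no_dip"))
  n <- length(speed)
  i <- imin
  while (i <= n) {
    if (speed[i] >= thr) {
      # dwell: every sample within [t_i, t_i + dwell] must stay recovered
      win <- which(time >= time[i] & time <= time[i] + dwell)
      if (all(speed[win] >= thr)) {
        if (interpolate && i > 1 && speed[i - 1] < thr) {
          frac <- (thr - speed[i - 1]) / (speed[i] - speed[i - 1])
          return(time[i - 1] + frac * (time[i] - time[i - 1]))
        }
        return(time[i])
      }
      i <- max(win[which(speed[win] < thr)]) + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(NA_real_, reason = "censored")
}

#' Per-frame metric series of a simulation
#'
#' Ensemble mean |vx| (finite-difference displacement of beads present in
#' consecutive frames, matched by particle id), nematic order `Sx`, shape
#' factor `SF`, mean chain length, bead/chain counts, cumulative
#' spawned/escaped bead ledger, and max radial dilation per recorded frame.
#'
#' @param sim an `axon_sim` from [run_simulation()].
#' @return data.frame with one row per frame.
#' @export
metric_series <- function(sim) {
  n <- length(sim$times)
  rm_ <- sim$params$rm
  speed <- rep(NA_real_, n)
  Sx <- rep(NA_real_, n)
  SF <- rep(NA_real_, n)
  mcl <- rep(NA_real_, n)
  n_beads <- integer(n)
  n_chains <- integer(n)
  for (i in seq_len(n)) {
    fr <- sim$frames[[i]]
    n_beads[i] <- nrow(fr$pos)
    n_chains[i] <- length(unique(fr$cid))
    if (n_beads[i] > 0) {
      b <- sim_frame(sim, i)
      Sx[i] <- as.numeric(nematic_order_x(b))
      SF[i] <- shape_factor(b, rm = rm_)
      mcl[i] <- mean_chain_length(b)
    }
    if (i > 1) {
      prev <- sim$frames[[i - 1]]
      common <- intersect(fr$pid, prev$pid)
      if (length(common) > 0) {
        x_now <- fr$pos[match(common, fr$pid), 1]
        x_prev <- prev$pos[match(common, prev$pid), 1]
        dt_out <- sim$times[i] - sim$times[i - 1]
        speed[i] <- mean(abs(x_now - x_prev) / dt_out)
      }
    }
  }
  data.frame(time = sim$times, mean_speed_x = speed, Sx = Sx, SF = SF,
             mean_chain_length = mcl, n_beads = n_beads, n_chains = n_chains,
             spawned = sim$spawned, escaped = sim$escaped,
             max_dilation = sim$max_dilation)
}

#' Scalar summary of a simulation
#'
#' Derived scalars of the metric series: the relief time, the minimum
#' nematic order and the shape factor at that time, the minimum ensemble
#' speed, and the peak max radial dilation.
#'
#' @param sim an `axon_sim`.
#' @param metrics optional precomputed [metric_series()].
#' @param threshold,dwell,interpolate passed to [relief_time()].
#' @return list of scalars; censored/undefined entries are flagged `NA`.
#' @export
sim_summary <- function(sim, metrics = NULL, threshold = 0.95, dwell = 1,
                        interpolate = FALSE) {
  if (is.null(metrics)) metrics <- metric_series(sim)
  v0 <- mean(c(sim$params$va, sim$params$vr))
  tau <- relief_time(metrics$time, metrics$mean_speed_x, v0,
                     threshold = threshold, dwell = dwell,
                     interpolate = interpolate)
  # configurational scalars are read while the axon is populated (at least
  # half the peak concurrent bead count), not from the sparse tail of
  # partially escaped chains
  ok <- is.finite(metrics$Sx) & metrics$n_beads >= 0.5 * max(metrics$n_beads)
  min_Sx <- if (any(ok)) min(metrics$Sx[ok]) else NA_real_
  SF_at <- if (any(ok)) metrics$SF[ok][which.min(metrics$Sx[ok])] else NA_real_
  list(tau_relieve = tau,
       min_Sx = min_Sx,
       SF_at_min_Sx = SF_at,
       min_speed = suppressWarnings(min(metrics$mean_speed_x, na.rm = TRUE)),
       peak_dilation = max(metrics$max_dilation),
       n_fission = sum(sim$events$type == "fission"),
       n_fusion = sum(sim$events$type == "fusion"))
}
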