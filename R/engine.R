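#' Run a full transport simulation
#'
#' Executes the complete protocol: mitochondria are generated at both axon
#' ends (anterograde at x = 0, retrograde at x = L, random cross-section
#' placement) at the configured cadence until the bead budget
#' ([bead_budget()]) is exhausted; each step applies fission/fusion,
#' assembles chain bending/spring/steric forces and bead-membrane WCA
#' contact forces (plus membrane bending, area elasticity and cytoskeletal
#' forces in deformable mode), advances everything with a forward-Euler
#' overdamped update, and removes beads that leave the axon. Runs are
#' deterministic given `(params, seed)`.
#'
#' @param params a [sim_params()] object.
#' @param mesh optional pre-built [build_cylinder_mesh()]; by default built
#'   from `params`.
#' @param record_mesh record membrane node frames (default: only in
#'   deformable mode).
#' @return an object of class `axon_sim`: recorded frame times, bead frames
#'   (positions in um), per-frame max radial dilation, membrane node frames,
#'   lifecycle event log, spawn/escape counters and diagnostics.
#' @examples
#' \donttest{
#' p <- sim_params(phi_fraction = 0.3, t_end = 10, seed = 1)
#' sim <- run_simulation(p)
#' ms <- metric_series(sim)
#' head(ms)
#' }
#' @export
run_simulation <- function(params, mesh = NULL, record_mesh = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(mesh))
    mesh <- build_cylinder_mesh(r0_a = params$r0_a, L = params$L,
                                ring_spacing = params$ring_spacing,
                                nodes_per_ring = params$nodes_per_ring,
                                actin_period = params$actin_period)
  if (is.null(record_mesh)) record_mesh <- params$mode == "deformable"
  nd <- nondimensionalize(params)
  budget <- bead_budget(params$phi_fraction, params$r0_a, params$L, params$rm)
  n_steps <- as.integer(round(nd$t_end / nd$dt))
  output_every <- max(1L, as.integer(round(nd$output_interval / nd$dt)))
  cadence_steps <- max(1L, as.integer(round(nd$generation_interval / nd$dt)))
  cfg <- list(dt = nd$dt, n_steps = n_steps, output_every = output_every,
              mesh_stride = params$mesh_output_stride,
              cadence_steps = cadence_steps,
              n_chain = params$n_chain, budget = budget,
              initial_pairs = params$initial_pairs,
              max_attempts = params$max_spawn_attempts,
              spawn_force = params$spawn_policy == "force",
              refill = params$refill,
              deformable = params$mode == "deformable",
              record_mesh = record_mesh,
              L = nd$L, rm = nd$rm, r_spawn = nd$r_spawn,
              va = nd$va, vr = nd$vr,
              gamma_m = nd$gamma_m, gamma_a = nd$gamma_a,
              kb_mito = nd$kb_mito, ks_mito = nd$ks_mito, kM = nd$kM,
              phi0 = nd$phi0, kb_mem = nd$kb_mem, kAE = nd$kAE,
              kS = nd$kS, kA = nd$kA,
              kfission = nd$kfission, kfusion = nd$kfusion,
              rfusion = nd$rfusion, cos_cutoff = nd$cos_cutoff,
              instab_disp = nd$rm)
  set.seed(params$seed)
  raw <- cpp_run_simulation(cfg, mesh_nondim(mesh, params$r0_a))
  sc <- attr(nd, "scales")
  r0 <- sc$length_um
  t0 <- sc$time_s
  frames <- lapply(raw$frames, function(fr) {
    list(pos = fr$pos * r0, pid = fr$pid, cid = fr$cid, dir = fr$dir)
  })
  sim <- list(times = raw$times * t0,
              frames = frames,
              max_dilation = raw$dilation,
              spawned = raw$spawned,
              escaped = raw$escaped,
              mesh_times = raw$mesh_times * t0,
              mesh_frames = lapply(raw$mesh_frames, function(m) m * r0),
              final_mesh = raw$final_mesh * r0,
              events = {
                ev <- events_df(raw$events)
                ev$time <- ev$time * t0
                ev$x <- ev$x * r0
                ev
              },
              diagnostics = raw$diagnostics,
              budget = budget,
              mesh = mesh,
              params = params)
  class(sim) <- "axon_sim"
  sim
}

#' @export
print.axon_sim <- function(x, ...) {
  n_fr <- length(x$times)
  last <- x$frames[[n_fr]]
  cat(sprintf("axon_sim: %d frames over %.2f s (%s mode, seed %d)\n",
              n_fr, max(x$times), x$params$mode, x$params$seed))
  cat(sprintf("  bead budget %d; spawned %d, escaped %d, %d in axon at t_end\n",
              x$budget, x$spawned[n_fr], x$escaped[n_fr], nrow(last$pos)))
  cat(sprintf("  lifecycle events: %d fission, %d fusion\n",
              sum(x$events$type == "fission"), sum(x$events$type == "fusion")))
  if (any(x$max_dilation > 0))
    cat(sprintf("  peak max radial dilation: %.1f%%\n",
                100 * max(x$max_dilation)))
  invisible(x)
}

#' Bead table of one recorded frame
#'
#' @param sim an `axon_sim`.
#' @param frame frame index (1-based; `length(sim$times)` frames exist).
#' @return a [bead_table()] in um.
#' @export
sim_frame <- function(sim, frame) {
  fr <- sim$frames[[frame]]
  if (nrow(fr$pos) == 0) {
    b <- data.frame(particle_id = integer(0), chain_id = integer(0),
                    direction = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), stringsAsFactors = FALSE)
    attr(b, "rm") <- sim$params$rm
    class(b) <- c("bead_table", "data.frame")
    return(b)
  }
  bead_table(fr$pos, chain_id = fr$cid, direction = int_to_dir(fr$dir),
             particle_id = fr$pid, rm = sim$params$rm)
}

#' Run an ensemble of simulations over seeds
#'
#' Repeats [run_simulation()] with seeds `base_seed + 0:(n_seeds-1)` and the
#' same parameters otherwise, mirroring the convention of reporting the mean
#' and standard deviation over repeated stochastic realizations.
#'
#' @param params a [sim_params()].
#' @param n_seeds number of replicate runs.
#' @param base_seed seed of the first replicate (default `params$seed`).
#' @param keep_sims keep the full `axon_sim` objects (memory-heavy); if
#'   `FALSE` only metric series and summaries are kept.
#' @return list with `summaries` (one [sim_summary()] per run), `metrics`
#'   (one [metric_series()] per run), `seeds`, and optionally `sims`.
#' @export
run_ensemble <- function(params, n_seeds = 5, base_seed = params$seed,
                         keep_sims = FALSE) {
  seeds <- base_seed + seq_len(n_seeds) - 1L
  metrics <- vector("list", n_seeds)
  summaries <- vector("list", n_seeds)
  sims <- if (keep_sims) vector("list", n_seeds) else NULL
  mesh <- build_cylinder_mesh(r0_a = params$r0_a, L = params$L,
                              ring_spacing = params$ring_spacing,
                              nodes_per_ring = params$nodes_per_ring,
                              actin_period = params$actin_period)
  for (i in seq_len(n_seeds)) {
    p <- params
    p$seed <- as.integer(seeds[i])
    sim <- run_simulation(p, mesh = mesh)
    metrics[[i]] <- metric_series(sim)
    summaries[[i]] <- sim_summary(sim)
    if (keep_sims) sims[[i]] <- sim
  }
  out <- list(seeds = seeds, metrics = metrics, summaries = summaries,
              sims = sims, params = params)
  class(out) <- "axon_ensemble"
  out
}

#' Aggregate scalar summaries over an ensemble
#'
#' @param ens an `axon_ensemble` from [run_ensemble()].
#' @return data.frame with mean, sd and n per scalar summary quantity
#'   (NA-censored runs dropped, their count reported).
#' @export
ensemble_summary <- function(ens) {
  fields <- c("tau_relieve", "min_Sx", "SF_at_min_Sx", "peak_dilation",
              "min_speed")
  rows <- lapply(fields, function(f) {
    v <- vapply(ens$summaries, function(s) as.numeric(s[[f]]), numeric(1))
    data.frame(quantity = f, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)),
               n_censored = sum(is.na(v)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
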