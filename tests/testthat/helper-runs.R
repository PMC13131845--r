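# Lazy cache for the heavier phenomenology runs shared across acceptance
# test blocks. Keyed by condition; each condition is computed once per
# test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

# fixed-axon jamming run; returns the scalar summary plus the metric series
jam_run <- function(phi, n_chain, kb_mito, seed, t_end = 60) {
  p <- sim_params(phi_fraction = phi, n_chain = n_chain, kb_mito = kb_mito,
                  t_end = t_end, seed = seed)
  sim <- run_simulation(p)
  ms <- metric_series(sim)
  list(summary = sim_summary(sim, ms), metrics = ms, params = p)
}

jam_ensemble <- function(phi, n_chain, kb_mito, seeds, t_end = 60) {
  key <- sprintf("jam_%g_%d_%g_%s_%g", phi, n_chain, kb_mito,
                 paste(seeds, collapse = "-"), t_end)
  cached(key, lapply(seeds, function(s) jam_run(phi, n_chain, kb_mito, s,
                                                t_end)))
}

# relief times with right-censored runs entered at their lower bound t_end
tau_of <- function(runs, t_end = 60) {
  vapply(runs, function(r) {
    tau <- r$summary$tau_relieve
    if (is.na(tau)) t_end else as.numeric(tau)
  }, numeric(1))
}

min_speed_of <- function(runs) {
  vapply(runs, function(r) r$summary$min_speed, numeric(1))
}

# deformable-membrane swelling run at the desk-scale configuration
swell_run <- function(n_chain, seed) {
  key <- sprintf("swell_%d_%d", n_chain, seed)
  cached(key, {
    p <- sim_params(phi_fraction = 0.3, n_chain = n_chain, kb_mito = 1e-19,
                    mode = "deformable", t_end = 20, dt = 2.5e-4,
                    nodes_per_ring = 36L, ring_spacing = 0.05, seed = seed)
    sim <- run_simulation(p)
    list(peak_dilation = max(sim$max_dilation),
         summary = sim_summary(sim))
  })
}

# pooled standard deviation for the ordering-with-ties comparisons
pooled_sd <- function(a, b) {
  sqrt((stats::var(a) * (length(a) - 1) + stats::var(b) * (length(b) - 1)) /
         (length(a) + length(b) - 2))
}
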