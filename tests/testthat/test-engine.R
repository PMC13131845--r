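# Short protocol-level runs; heavier phenomenology runs live in
# test-acceptance.R.

fast_params <- function(...) {
  sim_params(nodes_per_ring = 24L, ring_spacing = 0.1, ...)
}

test_that("generated chains have the prescribed spawn geometry", {
  p <- fast_params(phi_fraction = 0.3, n_chain = 5L, t_end = 0.1, seed = 3)
  sim <- run_simulation(p)
  b0 <- sim_frame(sim, 1)  # frame recorded right after initial generation
  cv <- chain_views(b0)
  expect_identical(sort(unique(b0$direction)),
                   c("anterograde", "retrograde"))
  for (ch in cv$chain_id) {
    beads <- b0[b0$chain_id == ch, ]
    rm_ <- p$rm
    if (beads$direction[1] == "anterograde") {
      expect_equal(beads$x, seq(0, by = 2 * rm_, length.out = 5))
    } else {
      expect_equal(beads$x, seq(p$L, by = -2 * rm_, length.out = 5))
    }
    # one shared random cross-section position per chain, inside the lumen
    expect_identical(length(unique(beads$y)), 1L)
    expect_identical(length(unique(beads$z)), 1L)
    expect_lte(sqrt(beads$y[1]^2 + beads$z[1]^2), p$r0_a - p$rm)
  }
})

test_that("cross-section placement is uniform over the spawn disk", {
  set.seed(123)
  yz <- axomito:::cpp_sample_disk(10000L, 0.375)
  r <- sqrt(rowSums(yz^2))
  # uniform-disk radial law: P(R <= r) = (r/rmax)^2
  ks <- stats::ks.test(r, function(q) pmin(1, (q / 0.375)^2))
  expect_gt(ks$p.value, 0.01)
  ang <- atan2(yz[, 2], yz[, 1])
  ks2 <- stats::ks.test(ang, "punif", -pi, pi)
  expect_gt(ks2$p.value, 0.01)
})

test_that("the bead ledger is exact and the budget is never exceeded", {
  p <- fast_params(phi_fraction = 0.3, n_chain = 5L, t_end = 12, seed = 1)
  sim <- run_simulation(p)
  ms <- metric_series(sim)
  expect_true(all(ms$spawned - ms$escaped == ms$n_beads))
  expect_lte(max(ms$spawned), 81)
  expect_lte(max(ms$n_beads), 81)
})

test_that("identical parameters and seed reproduce bit-identical output", {
  p <- fast_params(phi_fraction = 0.3, t_end = 3, k_fission = 1,
                   k_fusion = 1, seed = 11)
  s1 <- run_simulation(p)
  s2 <- run_simulation(p)
  expect_identical(metric_series(s1), metric_series(s2))
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$events, s2$events)
})

test_that("a lone chain free-streams out of the axon at the expected time", {
  # tiny budget: only one 5-bead chain fits, no lifecycle, fixed axon.
  # A widened wall mesh guarantees the chain never touches the membrane, so
  # the closed-form free-streaming limit applies whatever the spawn radius.
  p <- fast_params(phi_fraction = 0.02, n_chain = 5L, t_end = 12,
                   initial_pairs = 1L, seed = 2)
  expect_identical(bead_budget(0.02), 5L)
  wide <- build_cylinder_mesh(r0_a = 1, L = p$L, ring_spacing = 0.1,
                              nodes_per_ring = 24L)
  sim <- run_simulation(p, mesh = wide)
  ms <- metric_series(sim)
  # streams at exactly v0 while fully inside
  inside <- which(ms$n_beads == 5 & ms$time > 0.2 & ms$time < 6)
  expect_equal(ms$mean_speed_x[inside], rep(0.5, length(inside)),
               tolerance = 1e-9)
  # rear bead starts at x = 0, so the chain has fully left at t = L/va
  t_empty <- ms$time[which(ms$n_beads == 0)[1]]
  expect_lt(abs(t_empty - p$L / p$va), p$generation_interval + 0.1)
})

test_that("beads are removed bead-wise as chains cross the boundary", {
  p <- fast_params(phi_fraction = 0.02, n_chain = 5L, t_end = 12,
                   initial_pairs = 1L, seed = 2)
  wide <- build_cylinder_mesh(r0_a = 1, L = p$L, ring_spacing = 0.1,
                              nodes_per_ring = 24L)
  sim <- run_simulation(p, mesh = wide)
  ms <- metric_series(sim)
  partial <- ms$n_beads[ms$n_beads > 0 & ms$n_beads < 5]
  expect_gt(length(partial), 0)  # the chain shortens one bead at a time
  expect_true(all(diff(ms$n_beads[ms$n_beads != 5][-1]) <= 0))
})

test_that("gross timestep violation aborts with a diagnostic", {
  p <- fast_params(phi_fraction = 0.3, t_end = 1, dt = 0.2, seed = 1)
  expect_error(suppressWarnings(run_simulation(p)), "instability|moved more")
})

test_that("metrics recomputed from saved trajectory files are bit-identical", {
  p <- fast_params(phi_fraction = 0.3, t_end = 4, seed = 5)
  sim <- run_simulation(p)
  path <- tempfile(fileext = ".csv")
  write_bead_frames(sim, path)
  back <- read_bead_frames(path, rm = p$rm)
  expect_identical(back$times, sim$times)
  for (i in seq_along(sim$times)) {
    fr <- sim$frames[[i]]
    if (nrow(fr$pos) == 0) next
    fb <- back$frames[[which(back$times == sim$times[i])]]
    expect_identical(fb$pos, unname(fr$pos))
    expect_identical(fb$pid, fr$pid)
    b1 <- sim_frame(sim, i)
    b2 <- bead_table(fb$pos, fb$cid, fb$dir, fb$pid, rm = p$rm)
    expect_identical(nematic_order_x(b2), nematic_order_x(b1))
    expect_identical(shape_factor(b2), shape_factor(b1))
  }
  unlink(path)
})
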