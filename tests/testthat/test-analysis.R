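rm_ <- 0.125

test_that("nematic order hits its analytic anchor values", {
  # all bonds along x
  expect_equal(as.numeric(nematic_order_x(make_straight_chain(5))), 1)
  # all bonds perpendicular to x
  perp <- make_straight_chain(5, axis = c(0, 1, 0))
  expect_equal(as.numeric(nematic_order_x(perp)), -0.5)
  # isotropic bond orientations: <cos^2> = 1/3, Sx = 0 within 3 SE
  iso <- make_isotropic_bonds(100000, seed = 31)
  se <- 3 / 2 * sqrt(4 / 45) / sqrt(100000)  # sd of (3cos2-1)/2 for uniform
  expect_lt(abs(as.numeric(nematic_order_x(iso))), 3 * se)
  # no bonds: flagged NA, never 0
  singleton <- make_straight_chain(1)
  expect_true(is.na(nematic_order_x(singleton)))
  expect_identical(attr(nematic_order_x(singleton), "n_bonds"), 0L)
})

test_that("nematic order is invariant under translation and rotation about x", {
  set.seed(32)
  b <- make_isotropic_bonds(50, seed = 7)
  s0 <- as.numeric(nematic_order_x(b))
  b2 <- b
  b2$x <- b$x + 3; b2$y <- b$y - 1; b2$z <- b$z + 0.5
  expect_equal(as.numeric(nematic_order_x(b2)), s0)
  th <- 0.77
  b3 <- b
  b3$y <- cos(th) * b$y - sin(th) * b$z
  b3$z <- sin(th) * b$y + cos(th) * b$z
  expect_equal(as.numeric(nematic_order_x(b3)), s0, tolerance = 1e-12)
})

test_that("shape factor matches its worked values and invariances", {
  expect_equal(shape_factor(make_straight_chain(5)), 0.4)
  expect_equal(shape_factor(make_straight_chain(3)), 2 / 9)
  expect_equal(shape_factor(make_straight_chain(1)), 0)
  # rigid translation + rotation of a chain leaves SF unchanged
  b <- make_straight_chain(5, origin = c(1, 0.2, -0.3),
                           axis = c(1, 2, 2))
  expect_equal(shape_factor(b), 0.4, tolerance = 1e-12)
  # folding at constant bond length strictly decreases SF
  folded <- make_folded_chain(5, angle = 90)
  expect_lt(shape_factor(folded), 0.4)
  more_folded <- make_folded_chain(5, angle = 150)
  expect_lt(shape_factor(more_folded), shape_factor(folded))
  # mixed population: mean over chains
  mix <- rbind(make_straight_chain(5, chain_id = 1),
               make_straight_chain(1, chain_id = 2, origin = c(3, 0, 0),
                                   particle_id_start = 6))
  attr(mix, "rm") <- rm_
  class(mix) <- c("bead_table", "data.frame")
  expect_equal(shape_factor(mix), 0.2)
  expect_equal(mean_chain_length(mix), 3)
})

test_that("relief time handles dips, dwell, censoring and interpolation", {
  # constant series: no dip, flagged
  flat <- relief_time(0:10, rep(0.5, 11), v0 = 0.5)
  expect_true(is.na(flat))
  expect_identical(attr(flat, "reason"), "no_dip")
  # constructed crossing: first sample at/above 0.475 after the minimum is t=3
  tau <- relief_time(0:4, c(0.5, 0.2, 0.4, 0.48, 0.49), v0 = 0.5, dwell = 0)
  expect_equal(tau, 3)
  # never recovers: right-censored
  cens <- relief_time(0:4, c(0.5, 0.2, 0.3, 0.3, 0.3), v0 = 0.5)
  expect_true(is.na(cens))
  expect_identical(attr(cens, "reason"), "censored")
  # dwell rejects a single-sample spike recovery
  spiky <- c(0.5, 0.1, 0.48, 0.1, 0.1, 0.46, 0.48, 0.49, 0.5, 0.5, 0.5)
  tau_d <- relief_time(0:10, spiky, v0 = 0.5, dwell = 3)
  expect_equal(tau_d, 6)
  # piecewise-linear ramp: interpolated crossing within one sample interval
  tr <- make_speed_trace(v0 = 0.5, v_min = 0.2, t_min = 4, t_rec = 10,
                         dt = 0.8)
  exact <- 4 + 6 * (0.475 - 0.2) / 0.3
  tau_i <- relief_time(tr$time, tr$speed, 0.5, dwell = 0, interpolate = TRUE)
  expect_lt(abs(tau_i - exact), 0.8)
})

test_that("radial dilation measures fractional radius increase", {
  m <- make_mini_mesh(4, 8)
  expect_equal(max_radial_dilation(m$nodes, 0.5), 0)
  shifted <- m$nodes
  i <- which(m$mobile)[1]
  shifted[i, 2:3] <- shifted[i, 2:3] * 1.3
  expect_equal(max_radial_dilation(shifted, 0.5, m$mobile), 0.3)
  inflated <- m$nodes
  inflated[, 2:3] <- inflated[, 2:3] * 1.1
  expect_equal(max_radial_dilation(inflated, 0.5), 0.1)
})

test_that("ensemble summaries aggregate scalar metrics over seeds", {
  p <- sim_params(phi_fraction = 0.3, t_end = 8, nodes_per_ring = 24L,
                  ring_spacing = 0.1, seed = 1)
  ens <- run_ensemble(p, n_seeds = 2)
  expect_identical(ens$seeds, c(1L, 2L))
  agg <- ensemble_summary(ens)
  expect_true(all(c("mean", "sd", "n") %in% names(agg)))
  ms <- agg[agg$quantity == "min_speed", ]
  expect_true(ms$mean < 0.5 && ms$n == 2)
})
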