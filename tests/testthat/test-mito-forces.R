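rm_ <- 0.125

test_that("bending forces vanish for straight chains and short chains", {
  b <- make_straight_chain(3)
  expect_equal(max(abs(mito_bending_forces(b, 0.8))), 0)
  expect_equal(max(abs(mito_bending_forces(make_straight_chain(2), 0.8))), 0)
})

test_that("bending forces are the exact gradient of the bending energy", {
  kb <- 0.8
  # right-angle triple: tangents perpendicular
  pos <- rbind(c(0, 0, 0), c(2 * rm_, 0, 0), c(2 * rm_, 2 * rm_, 0))
  b <- bead_table(pos, 1, "anterograde", rm = rm_)
  f <- mito_bending_forces(b, kb)
  fd <- -num_grad(function(p) oracle_bend_energy(p, rep(1, 3), kb, rm_), pos,
                  h = 1e-8 * 2 * rm_)
  expect_lt(rel_err(f, fd, floor = 1e-6), 1e-5)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-14)
  # random wiggly chains (property over seeds)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6
    pos <- cbind(cumsum(c(0, rep(2 * rm_, n - 1))),
                 cumsum(c(0, rnorm(n - 1, 0, 0.06))),
                 cumsum(c(0, rnorm(n - 1, 0, 0.06))))
    b <- bead_table(pos, 1, "anterograde", rm = rm_)
    f <- mito_bending_forces(b, kb)
    fd <- -num_grad(function(p) oracle_bend_energy(p, rep(1, n), kb, rm_),
                    pos, h = 1e-7)
    expect_lt(rel_err(f, fd, floor = 1e-6), 1e-5)
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("coincident bonded beads raise a geometry error, not NaN", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.25, 0, 0))
  b <- data.frame(particle_id = 1:3, chain_id = 1L, direction = "anterograde",
                  x = pos[, 1], y = pos[, 2], z = pos[, 3])
  class(b) <- c("bead_table", "data.frame")
  attr(b, "rm") <- rm_
  expect_error(mito_bending_forces(b, 1, rm = rm_), "coincident")
  expect_error(mito_spring_forces(b, 100, rm = rm_), "coincident")
})

test_that("spring forces follow the Hookean law about the rest length 2rm", {
  # at rest: zero
  expect_equal(max(abs(mito_spring_forces(make_straight_chain(5), 100))), 0)
  # stretched by delta = 0.1*rm: attractive with magnitude ks*delta
  delta <- 0.1 * rm_
  pos <- rbind(c(0, 0, 0), c(2 * rm_ + delta, 0, 0))
  b <- bead_table(pos, 1, "anterograde", rm = rm_)
  f <- mito_spring_forces(b, 100)
  expect_equal(f[1, 1], 100 * delta)   # pulled toward +x partner
  expect_equal(f[2, 1], -100 * delta)
  # gradient consistency on a random stretched chain
  set.seed(3)
  pos <- cbind(cumsum(c(0, runif(4, 0.2, 0.3))), rnorm(5, 0, 0.02),
               rnorm(5, 0, 0.02))
  b <- bead_table(pos, 1, "anterograde", rm = rm_)
  f <- mito_spring_forces(b, 100)
  fd <- -num_grad(function(p) oracle_spring_energy(p, rep(1, 5), 100, rm_),
                  pos)
  expect_lt(rel_err(f, fd, floor = 1e-6), 1e-5)
})

test_that("steric forces are gated, pairwise-balanced and label-symmetric", {
  # gate closed beyond 2rm
  pos <- rbind(c(0, 0, 0), c(2.5 * rm_, 0, 0))
  b <- bead_table(pos, c(1, 2), "anterograde", rm = rm_)
  expect_equal(max(abs(mito_steric_forces(b, 40))), 0)
  # overlap rm: repulsive magnitude kM*rm on each, opposite
  pos <- rbind(c(0, 0, 0), c(rm_, 0, 0))
  b <- bead_table(pos, c(1, 2), "anterograde", rm = rm_)
  f <- mito_steric_forces(b, 40)
  expect_equal(f[1, 1], -40 * rm_)
  expect_equal(f[2, 1], 40 * rm_)
  expect_equal(colSums(f), c(0, 0, 0))
  # swapping the pair's labels negates both returned force rows
  b2 <- bead_table(pos[2:1, ], c(1, 2), "anterograde", rm = rm_)
  f2 <- mito_steric_forces(b2, 40)
  expect_equal(f2, -f, ignore_attr = TRUE)
  # second-nearest intra-chain neighbours do interact
  pos <- rbind(c(0, 0, 0), c(0.2, 0.1, 0), c(0.2, -0.1, 0))
  b3 <- bead_table(pos, 1, "anterograde", rm = rm_)
  d13 <- sqrt(sum((pos[3, ] - pos[1, ])^2))
  expect_lt(d13, 2 * rm_)
  expect_gt(max(abs(mito_steric_forces(b3, 40))), 0)
})

test_that("steric forces match the gradient of the overlap energy", {
  for (seed in 1:3) {
    set.seed(seed)
    pos <- matrix(runif(8 * 3, 0, 0.5), ncol = 3)
    b <- bead_table(pos, chain_id = rep(1:4, each = 2),
                    direction = "anterograde", rm = rm_)
    f <- mito_steric_forces(b, 40)
    fd <- -num_grad(function(p)
      oracle_steric_energy(p, rep(1:4, each = 2), 40, rm_), pos)
    expect_lt(rel_err(f, fd, floor = 1e-6), 1e-5)
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("WCA force is zero at the cutoff and matches the pair law inside", {
  phi0 <- 0.02
  node <- matrix(c(2^(1 / 6) * rm_, 0, 0), 1, 3)
  f <- wca_membrane_forces(matrix(0, 1, 3), node, phi0, rm_)
  expect_equal(max(abs(f$bead)), 0)
  expect_equal(max(abs(f$node)), 0)
  # separation rm: repulsive magnitude 24*phi0/rm (bracket 2 - 1 = 1)
  node <- matrix(c(rm_, 0, 0), 1, 3)
  f <- wca_membrane_forces(matrix(0, 1, 3), node, phi0, rm_)
  expect_equal(f$bead[1, 1], -24 * phi0 / rm_)
  expect_equal(f$node[1, ], -f$bead[1, ])  # action-reaction
  # gradient of the truncated-shifted potential on random pairs
  set.seed(11)
  beads <- matrix(runif(6, 0, 0.3), 2, 3)
  nodes <- beads[c(1, 2, 1), ] + matrix(rnorm(9, 0, 0.08), 3, 3)
  keep <- sqrt(rowSums((nodes - beads[c(1, 2, 1), ])^2)) > 0.6 * rm_
  nodes <- nodes[keep, , drop = FALSE]
  f <- wca_membrane_forces(beads, nodes, phi0, rm_)
  fdb <- -num_grad(function(p) oracle_wca_energy(p, nodes, phi0, rm_), beads,
                   h = 1e-9)
  expect_lt(rel_err(f$bead, fdb, floor = 1e-6), 1e-4)
})

test_that("near-contact WCA magnitude is capped and reported", {
  node <- matrix(c(0.4 * rm_, 0, 0), 1, 3)
  expect_warning(f <- wca_membrane_forces(matrix(0, 1, 3), node, 0.02, rm_),
                 "cap")
  capmag <- 24 * 0.02 / rm_ * (2 * 2^13 - 2^7)
  expect_equal(abs(f$bead[1, 1]), capmag)
})

test_that("internal forces conserve momentum on random crowded configurations", {
  for (seed in 1:5) {
    set.seed(seed)
    n_chains <- 6
    pos <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
      o <- runif(3, 0, 1)
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      sweep(outer(c(0, 1, 2, 3) * 0.22, d), 2, o, "+")
    }))
    b <- bead_table(pos, rep(seq_len(n_chains), each = 4),
                    "anterograde", rm = rm_)
    tot <- colSums(mito_bending_forces(b, 0.8) +
                   mito_spring_forces(b, 100) +
                   mito_steric_forces(b, 40))
    scale <- max(abs(mito_spring_forces(b, 100))) + 1
    expect_lt(max(abs(tot)) / scale, 1e-10)
  }
})

test_that("overdamped update combines drag response and propulsion exactly", {
  b <- make_straight_chain(1, direction = "anterograde")
  b2 <- advance_beads(b, matrix(0, 1, 3), dt = 0.1, va = 0.5, vr = 0.4)
  expect_equal(c(b2$x - b$x, b2$y, b2$z), c(0.05, 0, 0))
  r <- make_straight_chain(1, direction = "retrograde")
  r2 <- advance_beads(r, matrix(0, 1, 3), dt = 0.1, va = 0.5, vr = 0.4)
  expect_equal(r2$x - r$x, -0.04)
  # pure force, no propulsion
  f <- matrix(c(2, 0, 0), 1, 3)
  b3 <- advance_beads(b, f, dt = 0.1, gamma_m = 4, va = 0, vr = 0)
  expect_equal(b3$x - b$x, 0.05)
  expect_error(advance_beads(b, f, dt = 0), "dt")
})

test_that("an isolated straight chain translates rigidly at its propulsion speed", {
  b <- make_straight_chain(5, origin = c(1, 0.1, -0.2))
  f <- mito_bending_forces(b, 0.8) + mito_spring_forces(b, 100) +
    mito_steric_forces(b, 40)
  expect_equal(max(abs(f)), 0)
  b2 <- advance_beads(b, f, dt = 0.2, va = 0.5, vr = 0.5)
  expect_equal(b2$x, b$x + 0.1)
  expect_equal(b2$y, b$y)
  expect_equal(b2$z, b$z)
})
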