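test_that("built cylinder matches its analytic geometry", {
  m <- build_cylinder_mesh()
  # total triangle area within 2% of the analytic lateral area 2*pi*r0*L
  expect_lt(abs(m$A0 - 2 * pi * 0.5 * 3.8) / (2 * pi * 0.5 * 3.8), 0.02)
  # all initial node radii equal r0 to machine precision
  r <- sqrt(m$nodes[, 2]^2 + m$nodes[, 3]^2)
  expect_equal(r, rep(0.5, nrow(m$nodes)), tolerance = 1e-12)
  # outward-oriented faces
  expect_identical(nrow(m$faces), 2L * m$nodes_per_ring * (m$n_rings - 1L))
  # actin bonds form closed circumferential rings
  expect_identical(nrow(m$actin_bonds) %% m$nodes_per_ring, 0L)
  ring_of <- (m$actin_bonds - 1L) %/% m$nodes_per_ring
  expect_true(all(ring_of[, 1] == ring_of[, 2]))
  # spectrin bonds include the inter-ring lattice
  ring_of_s <- (m$spectrin_bonds - 1L) %/% m$nodes_per_ring
  expect_true(any(ring_of_s[, 1] != ring_of_s[, 2]))
  # the two rim rings are pinned
  expect_identical(sum(!m$mobile), 2L * m$nodes_per_ring)
})

test_that("flat planar patch has exactly zero bending force", {
  # two coplanar triangles sharing one hinge
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0))
  mesh <- list(nodes = nodes, faces = rbind(c(1, 2, 3), c(2, 1, 4)),
               hinges = matrix(c(1, 2, 3, 4), 1, 4),
               spectrin_bonds = matrix(0L, 0, 2), spectrin_rest = numeric(0),
               actin_bonds = matrix(0L, 0, 2), actin_rest = numeric(0),
               mobile = rep(TRUE, 4), A0 = 1)
  f <- membrane_bending_forces(mesh, kb = 2)
  expect_equal(max(abs(f)), 0)
})

test_that("hinge bending force is the exact gradient of the hinge energy", {
  kb <- 2.5
  set.seed(21)
  m <- make_mini_mesh(3, 6, r0_a = 0.5, length = 0.6)
  nodes <- m$nodes + matrix(rnorm(length(m$nodes), 0, 0.01), ncol = 3)
  f <- membrane_bending_forces(m, kb, nodes)
  fd <- -num_grad(function(nd) oracle_hinge_energy(nd, m$hinges, kb), nodes,
                  h = 1e-6)
  expect_lt(rel_err(f, fd, floor = 1e-5), 1e-5)
  # per-hinge internal balance: total force vanishes
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
})

test_that("degenerate zero-area triangles are reported by face", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0.5, -1, 0))
  mesh <- list(nodes = nodes, faces = rbind(c(1, 2, 3), c(2, 1, 4)),
               hinges = matrix(c(1, 2, 3, 4), 1, 4),
               spectrin_bonds = matrix(0L, 0, 2), spectrin_rest = numeric(0),
               actin_bonds = matrix(0L, 0, 2), actin_rest = numeric(0),
               mobile = rep(TRUE, 4), A0 = 1)
  expect_error(membrane_bending_forces(mesh, 1), "degenerate")
})

test_that("area elasticity restores the reference area", {
  m <- make_mini_mesh(4, 8)
  # unperturbed: prefactor (A/A0 - 1) = 0, all forces zero
  f0 <- area_elasticity_forces(m, kAE = 4e-3)
  expect_lt(max(abs(f0)), 1e-15)
  # uniformly inflated tube: inward radial force on mobile nodes
  inflated <- m$nodes
  inflated[, 2:3] <- inflated[, 2:3] * 1.1
  f <- area_elasticity_forces(m, kAE = 4e-3, nodes = inflated)
  radial <- f[, 2] * inflated[, 2] + f[, 3] * inflated[, 3]
  expect_true(all(radial[m$mobile] < 0))
  # exact gradient of (kAE/2)(A/A0 - 1)^2
  fd <- -num_grad(function(nd) {
    A <- oracle_tri_area(nd, m$faces)
    0.5 * 4e-3 * (A / m$A0 - 1)^2
  }, inflated, h = 1e-6)
  expect_lt(rel_err(f, fd, floor = 1e-8), 1e-5)
})

test_that("per-face area gradients cancel over the face's vertices", {
  set.seed(22)
  for (rep in 1:5) {
    tri <- matrix(rnorm(9), 3, 3)
    mesh <- list(nodes = tri, faces = matrix(1:3, 1, 3),
                 hinges = matrix(0L, 0, 4),
                 spectrin_bonds = matrix(0L, 0, 2), spectrin_rest = numeric(0),
                 actin_bonds = matrix(0L, 0, 2), actin_rest = numeric(0),
                 mobile = rep(TRUE, 3), A0 = oracle_tri_area(tri, matrix(1:3, 1, 3)))
    f <- area_elasticity_forces(mesh, kAE = 1, nodes = tri * 1.2)
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("cytoskeletal springs are Hookean about the built rest lengths", {
  m <- make_mini_mesh(4, 8)
  # constructed mesh is the equilibrium of the bond network
  expect_lt(max(abs(cytoskeleton_forces(m, kS = 2.06e-4, kA = 0.26))), 1e-14)
  # stretch one actin bond by moving a node radially
  delta <- 0.1 * m$actin_rest[1]
  i <- m$actin_bonds[1, 1]; j <- m$actin_bonds[1, 2]
  d <- (m$nodes[j, ] - m$nodes[i, ])
  d <- d / sqrt(sum(d^2))
  nodes <- m$nodes
  nodes[j, ] <- nodes[j, ] + delta * d
  # compare against the bond-energy gradient (several bonds change length)
  f <- cytoskeleton_forces(m, kS = 2.06e-4, kA = 0.26, nodes = nodes)
  fd <- -num_grad(function(nd)
    oracle_bond_energy(nd, m$spectrin_bonds, m$spectrin_rest, 2.06e-4) +
    oracle_bond_energy(nd, m$actin_bonds, m$actin_rest, 0.26), nodes,
    h = 1e-7)
  expect_lt(rel_err(f, fd, floor = 1e-8), 1e-5)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # isolated pair: magnitude kA*delta, attractive
  pair <- list(nodes = rbind(c(0, 0, 0), c(1 + 0.1, 0, 0)),
               faces = matrix(0L, 0, 3), hinges = matrix(0L, 0, 4),
               spectrin_bonds = matrix(0L, 0, 2), spectrin_rest = numeric(0),
               actin_bonds = matrix(1:2, 1, 2), actin_rest = 1,
               mobile = c(TRUE, TRUE), A0 = 1)
  fp <- cytoskeleton_forces(pair, kS = 1, kA = 0.26)
  expect_equal(fp[1, 1], 0.26 * 0.1)
  expect_equal(fp[2, 1], -0.26 * 0.1)
})

test_that("membrane update respects mode, mobility and the Euler law", {
  m <- make_mini_mesh(4, 8)
  f <- matrix(rnorm(length(m$nodes)), ncol = 3)
  # fixed-axon mode: bit-identical mesh whatever the forces
  expect_identical(advance_membrane(m, f, dt = 0.1, mode = "fixed_axon")$nodes,
                   m$nodes)
  # deformable: r + dt*F/gamma for mobile nodes, pinned rims frozen
  m2 <- advance_membrane(m, f, dt = 0.1, gamma_a = 2, mode = "deformable")
  mob <- m$mobile
  expect_equal(m2$nodes[mob, ], m$nodes[mob, ] + 0.1 * f[mob, ] / 2)
  expect_identical(m2$nodes[!mob, ], m$nodes[!mob, ])
  expect_error(advance_membrane(m, f, dt = -1), "dt")
})

test_that("the built composite is quasi-stationary under its own forces", {
  # reduced-unit mini tube evolved under bending + area + cytoskeleton only:
  # the construction state is the calibrated rest state, so drift stays small
  p <- sim_params(phi_fraction = 0.01, n_chain = 1L, t_end = 5,
                  mode = "deformable", nodes_per_ring = 24L,
                  ring_spacing = 0.1, initial_pairs = 0L, seed = 1)
  p$generation_interval <- 1e6  # no mitochondria ever generated
  sim <- run_simulation(p)
  disp <- max(abs(sim$final_mesh - sim$mesh$nodes))
  expect_lt(disp / p$r0_a, 0.02)  # < 2% of the radius over 5 s
})
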