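rm_ <- 0.125

two_collinear_chains <- function(gap = 1.05 * 2 * rm_, angle = 0) {
  a <- make_straight_chain(3, chain_id = 1)
  ax <- c(cos(angle * pi / 180), sin(angle * pi / 180), 0)
  b <- make_straight_chain(3, chain_id = 2, particle_id_start = 4,
                           origin = c(2 * 2 * rm_ + gap, 0, 0), axis = ax)
  out <- rbind(a, b)
  attr(out, "rm") <- rm_
  class(out) <- c("bead_table", "data.frame")
  out
}

test_that("zero rates leave chain assignments bit-identical", {
  b <- two_collinear_chains()
  set.seed(1)
  f1 <- fission_step(b, k_fission = 0, dt = 1)
  f2 <- fusion_step(f1$beads, k_fusion = 0, dt = 1)
  expect_identical(f2$beads$chain_id, b$chain_id)
  expect_identical(f2$beads$x, b$x)
  expect_identical(nrow(f1$events) + nrow(f2$events), 0L)
})

test_that("a certain gate splits every multi-bead chain, conserving beads", {
  set.seed(2)
  b <- rbind(make_straight_chain(5, chain_id = 1),
             make_straight_chain(1, chain_id = 2, origin = c(3, 0, 0),
                                 particle_id_start = 6))
  attr(b, "rm") <- rm_
  class(b) <- c("bead_table", "data.frame")
  out <- fission_step(b, k_fission = 1, dt = 1)  # dt*k >= 1 >= p always
  expect_identical(nrow(out$beads), 6L)                    # bead conservation
  expect_identical(out$beads$particle_id, b$particle_id)   # ids untouched
  expect_identical(length(unique(out$beads$chain_id)), 3L) # 5-chain split once
  expect_identical(out$events$type, "fission")
  # singleton never fissions
  expect_false(2L %in% out$events$chain_a)
  # direction inherited by both fragments
  expect_identical(unique(out$beads$direction), "anterograde")
})

test_that("fission counts follow the per-chain binomial expectation", {
  n_chains <- 20
  b <- do.call(rbind, lapply(seq_len(n_chains), function(i)
    make_straight_chain(5, chain_id = i, origin = c(0, 3 * i, 0),
                        particle_id_start = 5 * (i - 1) + 1)))
  attr(b, "rm") <- rm_
  class(b) <- c("bead_table", "data.frame")
  p_gate <- 0.3
  n_rep <- 2000
  set.seed(4)
  counts <- vapply(seq_len(n_rep), function(r)
    nrow(fission_step(b, k_fission = p_gate, dt = 1)$events), numeric(1))
  expected <- n_chains * p_gate
  se <- sqrt(n_chains * p_gate * (1 - p_gate) / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("high fission rate drives mean chain length to one", {
  b <- make_straight_chain(5)
  set.seed(5)
  for (i in 1:10) b <- fission_step(b, k_fission = 1, dt = 1)$beads
  expect_equal(mean_chain_length(b), 1)
  expect_identical(sort(b$particle_id), 1:5)
})

test_that("fusion requires proximity, alignment and the rate gate", {
  set.seed(6)
  # all three gates satisfied: one merged chain with extended bond topology
  b <- two_collinear_chains(gap = 1.05 * 2 * rm_)
  out <- fusion_step(b, k_fusion = 1, dt = 1, r_fusion = 1.1 * 2 * rm_,
                     theta_cutoff = 30)
  expect_identical(length(unique(out$beads$chain_id)), 1L)
  expect_identical(nrow(out$beads), 6L)
  expect_identical(out$events$type, "fusion")
  cv <- chain_views(out$beads)
  expect_identical(cv$length, 6L)
  # 45-degree relative orientation exceeds the 30-degree cutoff
  b45 <- two_collinear_chains(gap = 1.05 * 2 * rm_, angle = 45)
  out45 <- fusion_step(b45, k_fusion = 1, dt = 1, theta_cutoff = 30)
  expect_identical(length(unique(out45$beads$chain_id)), 2L)
  # distance gate: same geometry, too far apart
  bfar <- two_collinear_chains(gap = 3 * 2 * rm_)
  outf <- fusion_step(bfar, k_fusion = 1, dt = 1)
  expect_identical(length(unique(outf$beads$chain_id)), 2L)
  # rate gate: k_fusion = 0 never fuses
  out0 <- fusion_step(b, k_fusion = 0, dt = 1)
  expect_identical(length(unique(out0$beads$chain_id)), 2L)
})

test_that("antiparallel head-on chains can fuse (nematic orientation test)", {
  # end-to-end axes point in opposite directions; the axis angle is 0
  b <- make_head_on_pair(gap = 1.05 * 2 * rm_, n_chain = 3)
  set.seed(7)
  out <- fusion_step(b, k_fusion = 1, dt = 1)
  expect_identical(length(unique(out$beads$chain_id)), 1L)
  expect_identical(length(unique(out$beads$direction)), 1L)
})

test_that("mixed-direction fusion draws the surviving direction fairly", {
  b <- make_head_on_pair(gap = 1.05 * 2 * rm_, n_chain = 2)
  n_rep <- 4000
  set.seed(8)
  antero <- vapply(seq_len(n_rep), function(r) {
    out <- fusion_step(b, k_fusion = 1, dt = 1)
    out$beads$direction[1] == "anterograde"
  }, logical(1))
  se <- sqrt(0.25 / n_rep)
  expect_lt(abs(mean(antero) - 0.5), 3 * se)
})

test_that("ring-closure attempts are skipped and logged", {
  # a horseshoe chain whose two ends are within the fusion radius
  th <- seq(0, pi * 1.8, length.out = 10)
  r_arc <- 2 * rm_ / (2 * sin(diff(th)[1] / 2))  # bond length = 2rm on arc
  pos <- cbind(r_arc * cos(th), r_arc * sin(th), 0)
  b <- bead_table(pos, 1, "anterograde", rm = rm_)
  gap <- sqrt(sum((pos[10, ] - pos[1, ])^2))
  expect_lt(gap, 1.1 * 2 * rm_)
  set.seed(9)
  out <- fusion_step(b, k_fusion = 1, dt = 1, theta_cutoff = 180)
  expect_identical(length(unique(out$beads$chain_id)), 1L)
  expect_gte(out$ring_skips, 1)
  expect_true("ring_skip" %in% out$events$type)
})

test_that("fission weakly decreases and fusion weakly increases chain length", {
  set.seed(10)
  b <- two_collinear_chains()
  before <- mean_chain_length(b)
  bf <- fission_step(b, k_fission = 0.5, dt = 1)$beads
  expect_lte(mean_chain_length(bf), before)
  bu <- fusion_step(b, k_fusion = 0.5, dt = 1)$beads
  expect_gte(mean_chain_length(bu), before)
})
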