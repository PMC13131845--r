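# Independent R-side energy functions and a central-difference gradient.
# These deliberately re-derive every energy from its definition so the C++
# force kernels are checked against an implementation they do not share.

num_grad <- function(energy, pos, h = 1e-7) {
  g <- matrix(0, nrow(pos), 3)
  for (v in seq_len(nrow(pos))) {
    for (d in 1:3) {
      pp <- pos; pp[v, d] <- pp[v, d] + h
      pm <- pos; pm[v, d] <- pm[v, d] - h
      g[v, d] <- (energy(pp) - energy(pm)) / (2 * h)
    }
  }
  g
}

# chain bending: U = kb/(8 rm) * theta^2 per interior triple
oracle_bend_energy <- function(pos, cid, kb, rm) {
  E <- 0
  for (ch in unique(cid)) {
    ix <- which(cid == ch)
    if (length(ix) < 3) next
    for (q in 2:(length(ix) - 1)) {
      i <- ix[q]; j <- ix[q - 1]; k <- ix[q + 1]
      t1 <- pos[i, ] - pos[j, ]; t1 <- t1 / sqrt(sum(t1^2))
      t2 <- pos[k, ] - pos[i, ]; t2 <- t2 / sqrt(sum(t2^2))
      th <- acos(max(-1, min(1, sum(t1 * t2))))
      E <- E + kb / (8 * rm) * th^2
    }
  }
  E
}

# chain stretching: U = ks/2 * (|r| - 2rm)^2 per bond
oracle_spring_energy <- function(pos, cid, ks, rm) {
  E <- 0
  for (q in seq_len(nrow(pos) - 1)) {
    if (cid[q] != cid[q + 1]) next
    L <- sqrt(sum((pos[q + 1, ] - pos[q, ])^2))
    E <- E + ks / 2 * (L - 2 * rm)^2
  }
  E
}

# steric: U = kM/2 * (|r| - 2rm)^2 for overlapping non-bonded pairs
oracle_steric_energy <- function(pos, cid, kM, rm) {
  E <- 0
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 && cid[i] == cid[j]) next
      L <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      if (L < 2 * rm) E <- E + kM / 2 * (L - 2 * rm)^2
    }
  }
  E
}

# WCA pair potential, length scale rm, cut and shifted at 2^(1/6) rm
oracle_wca_energy <- function(bead_pos, node_pos, phi0, rm) {
  E <- 0
  for (i in seq_len(nrow(bead_pos))) {
    for (j in seq_len(nrow(node_pos))) {
      r <- sqrt(sum((bead_pos[i, ] - node_pos[j, ])^2))
      if (r < 2^(1 / 6) * rm) {
        q6 <- (rm / r)^6
        E <- E + 4 * phi0 * (q6^2 - q6) + phi0
      }
    }
  }
  E
}

# membrane hinge bending: E = 2 kb e (1 - cos theta) / (A1 + A2) per hinge
oracle_hinge_energy <- function(nodes, hinges, kb) {
  crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  E <- 0
  for (h in seq_len(nrow(hinges))) {
    i <- hinges[h, 1]; j <- hinges[h, 2]; k <- hinges[h, 3]; l <- hinges[h, 4]
    N1 <- crossp(nodes[j, ] - nodes[i, ], nodes[k, ] - nodes[i, ])
    N2 <- crossp(nodes[i, ] - nodes[j, ], nodes[l, ] - nodes[j, ])
    n1 <- sqrt(sum(N1^2)); n2 <- sqrt(sum(N2^2))
    cth <- sum(N1 * N2) / (n1 * n2)
    e <- sqrt(sum((nodes[j, ] - nodes[i, ])^2))
    E <- E + 2 * kb * e * (1 - cth) / ((n1 + n2) / 2)
  }
  E
}

oracle_tri_area <- function(nodes, faces) {
  A <- 0
  for (f in seq_len(nrow(faces))) {
    u <- nodes[faces[f, 2], ] - nodes[faces[f, 1], ]
    v <- nodes[faces[f, 3], ] - nodes[faces[f, 1], ]
    A <- A + 0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                              u[3] * v[1] - u[1] * v[3],
                              u[1] * v[2] - u[2] * v[1])^2))
  }
  A
}

oracle_bond_energy <- function(nodes, bonds, rest, k) {
  E <- 0
  for (e in seq_len(nrow(bonds))) {
    L <- sqrt(sum((nodes[bonds[e, 2], ] - nodes[bonds[e, 1], ])^2))
    E <- E + k / 2 * (L - rest[e])^2
  }
  E
}

# relative error with a magnitude floor (forces near zero compared absolutely)
rel_err <- function(a, b, floor = 1e-10) {
  max(abs(a - b) / pmax(abs(b), floor))
}
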