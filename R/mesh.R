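#' Build the triangulated axonal membrane-cytoskeleton composite
#'
#' Constructs a closed-tube triangulation of a cylinder of radius `r0_a` and
#' length `L`: rings of `nodes_per_ring` nodes at axial intervals of
#' `ring_spacing`, adjacent rings rotated by half a circumferential step and
#' triangulated. Circumferential edges on every
#' `round(actin_period/ring_spacing)`-th ring are typed as actin bonds
#' (the periodic actin rings of the membrane skeleton); all remaining edges
#' are spectrin bonds. Rest lengths are measured from the built mesh so the
#' constructed cylinder is an exact mechanical equilibrium of the bond
#' network; the reference area `A0` is the built total triangle area. The two
#' terminal rings are pinned (`mobile = FALSE`) — the segment is an excised
#' portion of a longer axon.
#'
#' @param r0_a cylinder radius (um).
#' @param L cylinder length (um).
#' @param ring_spacing target axial node spacing (um); the actual spacing is
#'   `L/(n_rings-1)` with `n_rings = round(L/ring_spacing) + 1`.
#' @param nodes_per_ring circumferential node count (>= 3).
#' @param actin_period axial period of actin rings (um).
#' @param pin_ends pin the two boundary rings (default TRUE).
#' @return an object of class `membrane_mesh`: list with `nodes` (n x 3, um),
#'   `faces` (outward-oriented vertex triples), `hinges` (i, j, k, l per
#'   interior edge), `spectrin_bonds`/`actin_bonds` with per-bond rest
#'   lengths, `mobile` flags, total reference area `A0`, and the build
#'   parameters.
#' @export
build_cylinder_mesh <- function(r0_a = 0.5, L = 3.8, ring_spacing = 0.038,
                                nodes_per_ring = 48L, actin_period = 0.18,
                                pin_ends = TRUE) {
  if (ring_spacing <= 0 || r0_a <= 0 || L <= 0)
    stop("build_cylinder_mesh: geometry must be positive")
  if (nodes_per_ring < 3) stop("build_cylinder_mesh: need >= 3 nodes per ring")
  n_rings <- as.integer(round(L / ring_spacing)) + 1L
  if (n_rings < 2) stop("build_cylinder_mesh: need >= 2 rings")
  npr <- as.integer(nodes_per_ring)
  s <- L / (n_rings - 1)

  ring <- rep(seq_len(n_rings) - 1L, each = npr)
  slot <- rep(seq_len(npr) - 1L, times = n_rings)
  phi <- 2 * pi * (slot + 0.5 * (ring %% 2L)) / npr
  nodes <- cbind(x = ring * s, y = r0_a * cos(phi), z = r0_a * sin(phi))
  idx <- function(r, q) r * npr + (q %% npr) + 1L  # 0-based ring/slot -> row

  # strip triangulation between consecutive rings (half-step stagger)
  faces <- vector("list", n_rings - 1L)
  for (r in 0:(n_rings - 2L)) {
    q <- 0:(npr - 1L)
    A1 <- idx(r, q); A2 <- idx(r, q + 1L)
    B1 <- idx(r + 1L, q); B2 <- idx(r + 1L, q + 1L)
    if (r %% 2L == 0L) {
      f <- rbind(cbind(A1, A2, B1), cbind(A2, B2, B1))
    } else {
      f <- rbind(cbind(A1, A2, B2), cbind(A1, B2, B1))
    }
    faces[[r + 1L]] <- f
  }
  faces <- do.call(rbind, faces)
  dimnames(faces) <- NULL

  # enforce outward orientation: normal . radial > 0 at the face centroid
  v1 <- nodes[faces[, 2], ] - nodes[faces[, 1], ]
  v2 <- nodes[faces[, 3], ] - nodes[faces[, 1], ]
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  cen <- (nodes[faces[, 1], ] + nodes[faces[, 2], ] + nodes[faces[, 3], ]) / 3
  outward <- nrm[, 2] * cen[, 2] + nrm[, 3] * cen[, 3] > 0
  faces[!outward, 2:3] <- faces[!outward, 3:2]

  # edge table: every face contributes its 3 directed edges
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  face_of <- rep(seq_len(nrow(faces)), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  by_edge <- split(seq_along(key), key)
  n_faces_per_edge <- lengths(by_edge)
  if (any(n_faces_per_edge > 2))
    stop("build_cylinder_mesh: non-manifold edge")

  hinges <- matrix(0L, 0L, 4L)
  interior <- by_edge[n_faces_per_edge == 2L]
  if (length(interior)) {
    hinges <- t(vapply(interior, function(rows) {
      # orient the hinge by the first face's directed traversal of the edge
      r1 <- rows[1]; r2 <- rows[2]
      i <- ed[r1, 1]; j <- ed[r1, 2]
      f1 <- faces[face_of[r1], ]; f2 <- faces[face_of[r2], ]
      k <- f1[!(f1 %in% c(i, j))]
      l <- f2[!(f2 %in% c(i, j))]
      c(i, j, k, l)
    }, integer(4)))
    dimnames(hinges) <- NULL
  }

  # bond typing: circumferential edges on actin rings are actin, rest spectrin
  uniq_rows <- vapply(by_edge, `[`, integer(1), 1L)
  eu <- cbind(pmin(ed[uniq_rows, 1], ed[uniq_rows, 2]),
              pmax(ed[uniq_rows, 1], ed[uniq_rows, 2]))
  ring_of <- (eu - 1L) %/% npr
  circumferential <- ring_of[, 1] == ring_of[, 2]
  actin_every <- max(1L, as.integer(round(actin_period / s)))
  on_actin_ring <- circumferential & (ring_of[, 1] %% actin_every == 0L)
  blen <- sqrt(rowSums((nodes[eu[, 1], ] - nodes[eu[, 2], ])^2))
  actin_bonds <- eu[on_actin_ring, , drop = FALSE]
  actin_rest <- blen[on_actin_ring]
  spectrin_bonds <- eu[!on_actin_ring, , drop = FALSE]
  spectrin_rest <- blen[!on_actin_ring]

  A0 <- sum(0.5 * sqrt(rowSums(nrm^2)))
  mobile <- rep(TRUE, nrow(nodes))
  if (pin_ends) mobile[ring == 0L | ring == n_rings - 1L] <- FALSE

  m <- list(nodes = unname(nodes), faces = faces, hinges = hinges,
            spectrin_bonds = spectrin_bonds, spectrin_rest = spectrin_rest,
            actin_bonds = actin_bonds, actin_rest = actin_rest,
            mobile = mobile, A0 = A0, r0_a = r0_a, L = L,
            ring_spacing = s, nodes_per_ring = npr,
            n_rings = n_rings, actin_every = actin_every)
  class(m) <- "membrane_mesh"
  m
}

#' @export
print.membrane_mesh <- function(x, ...) {
  cat(sprintf(paste0("Triangulated membrane tube: %d nodes (%d rings x %d), ",
                     "%d faces, %d hinges\n"),
              nrow(x$nodes), x$n_rings, x$nodes_per_ring, nrow(x$faces),
              nrow(x$hinges)))
  cat(sprintf("  r0 = %g um, L = %g um, A0 = %.4f um^2\n", x$r0_a, x$L, x$A0))
  cat(sprintf("  bonds: %d spectrin (mean rest %.4g um), %d actin (mean rest %.4g um)\n",
              nrow(x$spectrin_bonds), mean(x$spectrin_rest),
              nrow(x$actin_bonds), mean(x$actin_rest)))
  cat(sprintf("  actin rings every %d rings; %d pinned rim nodes\n",
              x$actin_every, sum(!x$mobile)))
  invisible(x)
}

# internal: rescale a mesh into dimensionless engine units
mesh_nondim <- function(mesh, r0_a) {
  list(nodes = mesh$nodes / r0_a,
       faces = mesh$faces,
       hinges = mesh$hinges,
       spectrin_bonds = mesh$spectrin_bonds,
       spectrin_rest = mesh$spectrin_rest / r0_a,
       actin_bonds = mesh$actin_bonds,
       actin_rest = mesh$actin_rest / r0_a,
       mobile = mesh$mobile,
       A0 = mesh$A0 / r0_a^2)
}
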