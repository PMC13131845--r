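#' Construct a bead table
#'
#' The bead table is the state container for all mitochondrial beads: one row
#' per bead with its 3-D position (um at the interface), immutable
#' `particle_id`, mutable `chain_id`, and transport `direction`. Beads of a
#' chain occupy consecutive rows in spring-bond order; row adjacency within a
#' chain *is* the bond topology.
#'
#' @param position numeric matrix (n x 3) of bead centres.
#' @param chain_id integer chain labels; equal labels must be contiguous.
#' @param direction `"anterograde"` (+x propulsion) or `"retrograde"` (-x),
#'   one value per bead, constant within a chain; recycled if length 1.
#' @param particle_id unique integer ids; defaults to `seq_len(n)`.
#' @param rm bead radius (um), stored as an attribute.
#' @return a `data.frame` of class `bead_table` with columns `particle_id`,
#'   `chain_id`, `direction`, `x`, `y`, `z`.
#' @export
bead_table <- function(position, chain_id, direction, particle_id = NULL,
                       rm = 0.125) {
  position <- as.matrix(position)
  if (ncol(position) != 3) stop("bead_table: position must be n x 3")
  n <- nrow(position)
  chain_id <- as.integer(rep_len(chain_id, n))
  direction <- rep_len(as.character(direction), n)
  if (!all(direction %in% c("anterograde", "retrograde")))
    stop("bead_table: direction must be 'anterograde' or 'retrograde'")
  if (is.null(particle_id)) particle_id <- seq_len(n)
  b <- data.frame(particle_id = as.integer(particle_id),
                  chain_id = chain_id, direction = direction,
                  x = position[, 1], y = position[, 2], z = position[, 3],
                  stringsAsFactors = FALSE)
  attr(b, "rm") <- rm
  class(b) <- c("bead_table", "data.frame")
  validate_bead_table(b)
  b
}

#' Validate bead-table invariants
#'
#' Checks that particle ids are unique, each chain carries a single direction
#' label, chains are stored contiguously in bond order, and no bond is
#' stretched beyond the sanity bound `3 * 2rm`.
#'
#' @param beads a [bead_table()].
#' @param rm bead radius (um); defaults to the table's attribute.
#' @return the table, invisibly; errors on violation.
#' @export
validate_bead_table <- function(beads, rm = attr(beads, "rm")) {
  if (anyDuplicated(beads$particle_id))
    stop("bead_table: particle_id values must be unique")
  runs <- rle(beads$chain_id)
  if (anyDuplicated(runs$values))
    stop("bead_table: beads of a chain must occupy contiguous rows")
  dir_per_chain <- tapply(beads$direction, beads$chain_id,
                          function(d) length(unique(d)))
  if (any(dir_per_chain != 1))
    stop("bead_table: each chain must have exactly one direction label")
  if (!is.null(rm) && nrow(beads) > 1) {
    same <- beads$chain_id[-1] == beads$chain_id[-nrow(beads)]
    if (any(same)) {
      d <- sqrt(diff(beads$x)^2 + diff(beads$y)^2 + diff(beads$z)^2)[same]
      if (any(d >= 3 * 2 * rm))
        stop("bead_table: bonded beads further apart than 3 bead diameters")
    }
  }
  invisible(beads)
}

#' Per-chain summary of a bead table
#'
#' Derives the chain-level view: ordered bead ids (head-to-tail in bond
#' order), chain length, direction, end beads (the beads with at most one
#' intra-chain neighbour), and the end-to-end orientation axis.
#'
#' @param beads a [bead_table()].
#' @return a `data.frame` with one row per chain: `chain_id`, `length`,
#'   `direction`, `first_bead`, `last_bead`, and orientation components
#'   `ux`, `uy`, `uz` (unit end-to-end axis; the propulsion axis for
#'   singletons).
#' @export
chain_views <- function(beads) {
  validate_bead_table(beads)
  runs <- rle(beads$chain_id)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(runs$values)
  ux <- uy <- uz <- numeric(n)
  for (i in seq_len(n)) {
    a <- starts[i]; b <- ends[i]
    if (b > a) {
      v <- c(beads$x[b] - beads$x[a], beads$y[b] - beads$y[a],
             beads$z[b] - beads$z[a])
      nv <- sqrt(sum(v^2))
      if (nv > 0) v <- v / nv
    } else {
      v <- c(if (beads$direction[a] == "anterograde") 1 else -1, 0, 0)
    }
    ux[i] <- v[1]; uy[i] <- v[2]; uz[i] <- v[3]
  }
  data.frame(chain_id = runs$values,
             length = runs$lengths,
             direction = beads$direction[starts],
             first_bead = beads$particle_id[starts],
             last_bead = beads$particle_id[ends],
             ux = ux, uy = uy, uz = uz,
             stringsAsFactors = FALSE)
}

# internal: encode/decode direction for the C++ kernels
dir_to_int <- function(direction) {
  ifelse(direction == "anterograde", 1L, -1L)
}

int_to_dir <- function(d) {
  ifelse(d > 0, "anterograde", "retrograde")
}

bead_pos <- function(beads) {
  cbind(beads$x, beads$y, beads$z)
}

# internal: rebuild a bead_table from C++ output
beads_from_cpp <- function(lst, rm) {
  bead_table(lst$pos, chain_id = lst$cid, direction = int_to_dir(lst$dir),
             particle_id = lst$pid, rm = rm)
}
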