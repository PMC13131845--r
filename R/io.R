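# Plain-text trajectory output. All numeric columns are written with 17
# significant digits so that read-back reproduces the doubles bit-for-bit
# and metrics recomputed from files equal in-run metrics exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write bead trajectory frames to CSV
#'
#' One long table: frame index, time, particle/chain ids, direction, and
#' positions, full precision.
#'
#' @param sim an `axon_sim`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_bead_frames <- function(sim, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("frame,time,particle_id,chain_id,direction,x,y,z", con)
  for (i in seq_along(sim$times)) {
    fr <- sim$frames[[i]]
    if (nrow(fr$pos) == 0) next
    writeLines(paste(i, fmt_num(sim$times[i]), fr$pid, fr$cid,
                     int_to_dir(fr$dir),
                     fmt_num(fr$pos[, 1]), fmt_num(fr$pos[, 2]),
                     fmt_num(fr$pos[, 3]), sep = ","), con)
  }
  invisible(file)
}

#' Read bead trajectory frames written by [write_bead_frames()]
#'
#' @param file CSV path.
#' @param rm bead radius recorded into the rebuilt tables (um).
#' @return list with `times` and `frames` (lists of pos/pid/cid/dir),
#'   structurally matching `axon_sim$frames`.
#' @export
read_bead_frames <- function(file, rm = 0.125) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  frames <- lapply(split(seq_len(nrow(d)), d$frame), function(ix) {
    list(pos = cbind(d$x[ix], d$y[ix], d$z[ix]),
         pid = d$particle_id[ix], cid = d$chain_id[ix], dir = d$direction[ix])
  })
  times <- vapply(split(d$time, d$frame), `[`, numeric(1), 1L)
  list(times = unname(times), frames = unname(frames), rm = rm)
}

#' Write bead frames as extended XYZ
#'
#' One XYZ block per frame with columns particle_id, chain_id, direction,
#' x, y, z; readable by standard particle-trajectory viewers.
#'
#' @param sim an `axon_sim`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_xyz <- function(sim, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(sim$times)) {
    fr <- sim$frames[[i]]
    writeLines(as.character(nrow(fr$pos)), con)
    writeLines(sprintf("time=%s Properties=particle_id:chain_id:direction:pos",
                       fmt_num(sim$times[i])), con)
    if (nrow(fr$pos) > 0)
      writeLines(paste(fr$pid, fr$cid, int_to_dir(fr$dir),
                       fmt_num(fr$pos[, 1]),
                       fmt_num(fr$pos[, 2]), fmt_num(fr$pos[, 3])), con)
  }
  invisible(file)
}

#' Write a membrane mesh (or a node frame of it) as ASCII PLY
#'
#' @param mesh a `membrane_mesh`.
#' @param file output path.
#' @param nodes optional node positions overriding `mesh$nodes`.
#' @return the path, invisibly.
#' @export
write_mesh_ply <- function(mesh, file, nodes = mesh$nodes) {
  con <- file(file, "w")
  on.exit(close(con))
  nodes <- as.matrix(nodes)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(nodes)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmt_num(nodes[, 1]), fmt_num(nodes[, 2]),
                   fmt_num(nodes[, 3])), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(file)
}

#' Write the lifecycle event log as CSV
#'
#' @param sim an `axon_sim`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_event_log <- function(sim, file) {
  ev <- sim$events
  ev$time <- fmt_num(ev$time)
  ev$x <- fmt_num(ev$x)
  write.csv(ev, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the metric series as CSV
#'
#' @param metrics a [metric_series()] data.frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_metric_series <- function(metrics, file) {
  m <- metrics
  for (j in seq_along(m)) if (is.double(m[[j]])) m[[j]] <- fmt_num(m[[j]])
  write.csv(m, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the scalar summary as JSON
#'
#' @param summary a [sim_summary()] list.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_summary_json <- function(summary, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_summary_json requires the jsonlite package")
  jsonlite::write_json(summary, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}
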