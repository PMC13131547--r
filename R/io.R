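#' Save / load a configuration
#'
#' Configurations are stored as flat YAML mirroring the [sim_config()] field
#' names.  On load, unspecified fields take their defaults, unknown keys are
#' an error naming the key, and the result is re-validated; an empty file
#' yields the default configuration.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `load_config()` returns a [sim_config()].
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  do.call(sim_config, x)
}

# CSV with %.17g formatting: doubles survive the round trip bit-faithfully,
# integer id columns stay exact.
write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_bead_table <- function() {
  data.frame(frame = integer(0), time = numeric(0), particle_id = integer(0),
             chain_id = integer(0), polarity = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0), vx = numeric(0), vy = numeric(0),
             vz = numeric(0))
}

flatten_frames <- function(frames) {
  if (length(frames) == 0) return(empty_bead_table())
  beads <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    st <- fr$state
    n <- n_beads(st)
    if (n == 0) return(empty_bead_table())
    data.frame(frame = i, time = fr$time, particle_id = st$particle_id,
               chain_id = st$chain_id, polarity = st$polarity,
               x = st$pos[, 1], y = st$pos[, 2], z = st$pos[, 3],
               vx = fr$velocities[, 1], vy = fr$velocities[, 2],
               vz = fr$velocities[, 3])
  })
  do.call(rbind, beads)
}

#' Write / read a trajectory
#'
#' A run is stored as a directory: `config.yaml`, `series.csv` (the
#' observable time series), `beads.csv` (flattened frames at full double
#' precision), `nodes.csv` (membrane snapshots, deformable runs),
#' `meta.json`, and a `manifest.json` with md5 checksums of every file.  The
#' round trip is lossless: ids are exact and coordinates bit-faithful.
#'
#' @param traj a `mito_trajectory`.
#' @param dir output directory (created if needed).
#' @return `read_trajectory()` returns the reconstructed `mito_trajectory`.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  save_config(traj$config, file.path(dir, "config.yaml"))
  write_csv17(traj$series, file.path(dir, "series.csv"))
  write_csv17(flatten_frames(traj$frames), file.path(dir, "beads.csv"))
  frame_times <- vapply(traj$frames, `[[`, numeric(1), "time")
  nodeframes <- Filter(function(fr) !is.null(fr$nodes), traj$frames)
  if (length(nodeframes) > 0) {
    nd <- do.call(rbind, lapply(seq_along(nodeframes), function(i) {
      fr <- nodeframes[[i]]
      data.frame(frame = match(fr$time, frame_times), time = fr$time,
                 node = seq_len(nrow(fr$nodes)), x = fr$nodes[, 1],
                 y = fr$nodes[, 2], z = fr$nodes[, 3])
    }))
    write_csv17(nd, file.path(dir, "nodes.csv"))
  }
  meta <- list(t_inject_end = traj$t_inject_end, target_beads = traj$target_beads,
               injected = traj$injected, removed = traj$removed,
               mode = traj$mode, units = traj$units,
               frame_times = frame_times)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_run_manifest(dir, traj$config, started = t0)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  need <- file.path(dir, c("config.yaml", "series.csv", "beads.csv", "meta.json"))
  if (!all(file.exists(need)))
    stop("corrupted or truncated trajectory directory: missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "))
  config <- load_config(file.path(dir, "config.yaml"))
  series <- read.csv(file.path(dir, "series.csv"))
  beads <- read.csv(file.path(dir, "beads.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nodes_path <- file.path(dir, "nodes.csv")
  nodes <- if (file.exists(nodes_path)) read.csv(nodes_path) else NULL
  frames <- lapply(seq_along(meta$frame_times), function(i) {
    b <- beads[beads$frame == i, , drop = FALSE]
    st <- mito_state(cbind(b$x, b$y, b$z), b$chain_id, b$polarity, b$particle_id)
    nmat <- NULL
    if (!is.null(nodes)) {
      nb <- nodes[nodes$frame == i, , drop = FALSE]
      if (nrow(nb) > 0) nmat <- unname(cbind(nb$x, nb$y, nb$z))
    }
    structure(list(time = meta$frame_times[i], state = st,
                   velocities = unname(cbind(b$vx, b$vy, b$vz)), nodes = nmat),
              class = "trajectory_frame")
  })
  structure(list(config = config, series = series, frames = frames,
                 t_inject_end = meta$t_inject_end,
                 target_beads = meta$target_beads, injected = meta$injected,
                 removed = meta$removed, final_state = NULL,
                 final_nodes = NULL, mesh = NULL, mode = meta$mode,
                 units = meta$units), class = "mito_trajectory")
}

#' Export a bead snapshot as extended XYZ
#'
#' One record per bead: species tag, position (m), chain id and polarity.
#'
#' @param x a `trajectory_frame` or [mito_state()].
#' @param path output file.
#' @export
write_xyz <- function(x, path) {
  st <- if (inherits(x, "trajectory_frame")) x$state else x
  tm <- if (inherits(x, "trajectory_frame")) x$time else NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n_beads(st)), con)
  writeLines(sprintf(
    "Properties=species:S:1:pos:R:3:chain_id:I:1:polarity:I:1 time=%s", tm), con)
  if (n_beads(st) > 0)
    writeLines(sprintf("M %.17g %.17g %.17g %d %d", st$pos[, 1], st$pos[, 2],
                       st$pos[, 3], st$chain_id, st$polarity), con)
  invisible(path)
}

#' Export a mesh snapshot as legacy ASCII VTK
#'
#' Triangles plus a per-node scalar (by default the relative radial
#' displacement from `r_0a`).
#'
#' @param mesh an [build_axon_mesh()] mesh (or one with displaced nodes).
#' @param path output file.
#' @param scalars per-node scalar values; default radial dilation.
#' @export
write_mesh_vtk <- function(mesh, path, scalars = NULL) {
  nodes <- mesh$nodes
  faces <- mesh$faces
  if (is.null(scalars))
    scalars <- (sqrt(nodes[, 2]^2 + nodes[, 3]^2) - mesh$r_0a) / mesh$r_0a
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "axon membrane-MPS tube", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes[, 1], nodes[, 2], nodes[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(faces), 4L * nrow(faces)), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(nodes)),
               "SCALARS radial_dilation double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", scalars), con)
  invisible(path)
}

#' Run manifest
#'
#' `write_run_manifest()` records the full configuration, seed, package
#' version, wall time and an md5 checksum of every other file in the run
#' directory -- enough to re-run the simulation bit-identically with the same
#' code version.  `verify_run_manifest()` re-hashes the files and reports
#' whether they still match.
#'
#' @param dir run directory.
#' @param config the run's [sim_config()].
#' @param started ISO start time string.
#' @return `verify_run_manifest()` returns `TRUE`/`FALSE`.
#' @export
write_run_manifest <- function(dir, config, started = NA) {
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "mitojam",
    version = as.character(packageVersion("mitojam")),
    seed = config$seed,
    config = unclass(config),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run_manifest
#' @export
verify_run_manifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  files <- names(mf$files)
  sums <- tools::md5sum(file.path(dir, files))
  all(!is.na(sums)) && all(unname(sums) == unlist(mf$files))
}
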