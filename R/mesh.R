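#' Build the triangulated membrane-MPS tube
#'
#' Constructs the axonal boundary as a triangulated cylinder of radius `r_0a`
#' and length `L`, open at both ends.  Nodes sit on rings spaced `l_0` apart
#' axially, `n_c = round(2 pi r_0a / l_a)` nodes per ring, with alternating
#' rings rotated by half a step so the lattice is triangular.  Circumferential
#' bonds of the rings nearest to integer multiples of `ring_spacing` (the
#' membrane periodic skeleton's actin period) are actin edges; every other
#' lattice bond is spectrin.  Per-edge rest lengths, per-hinge reference
#' dihedrals and the reference area `A_0` are recorded from the built
#' geometry, so the fresh mesh is exactly stress-free.
#'
#' The two terminal node rings are pinned: the segment stands for a portion of
#' a longer axon, and free ends would curl under bending forces.
#'
#' @param r_0a tube radius (m).
#' @param L tube length (m).
#' @param l_0 axial ring spacing = spectrin lattice rest length (m).
#' @param l_a target circumferential (actin) rest length (m).
#' @param ring_spacing axial period of the actin rings (m).
#' @return An object of class `axon_mesh`.
#' @export
#' @examples
#' mesh <- build_axon_mesh(500e-9, 1e-6)
#' mesh$n_c                      # 48 nodes per ring
#' table(mesh$edge_type)
build_axon_mesh <- function(r_0a, L, l_0 = 38e-9, l_a = 65e-9,
                            ring_spacing = 180e-9) {
  stopifnot(r_0a > 0, L > 0, l_0 > 0, l_a > 0, ring_spacing > 0)
  n_c <- as.integer(round(2 * pi * r_0a / l_a))
  if (n_c < 3) stop("configuration error: fewer than 3 nodes per ring")
  n_rings <- as.integer(floor(L / l_0 + 1e-9)) + 1L
  if (n_rings < 2) stop("configuration error: fewer than 2 rings")

  ring <- rep(0:(n_rings - 1L), each = n_c)
  kk <- rep(0:(n_c - 1L), times = n_rings)
  theta <- 2 * pi * (kk + 0.5 * (ring %% 2)) / n_c
  nodes <- cbind(ring * l_0, r_0a * cos(theta), r_0a * sin(theta))

  nid <- function(r, k) r * n_c + (k %% n_c) + 1L   # 1-based node id
  faces <- vector("list", n_rings - 1L)
  ks <- 0:(n_c - 1L)
  for (r in 0:(n_rings - 2L)) {
    if (r %% 2 == 0) {
      # lower ring at integer angles, upper ring offset by +1/2
      t1 <- cbind(nid(r, ks), nid(r, ks + 1L), nid(r + 1L, ks))
      t2 <- cbind(nid(r, ks + 1L), nid(r + 1L, ks + 1L), nid(r + 1L, ks))
    } else {
      t1 <- cbind(nid(r, ks), nid(r, ks + 1L), nid(r + 1L, ks + 1L))
      t2 <- cbind(nid(r, ks), nid(r + 1L, ks + 1L), nid(r + 1L, ks))
    }
    faces[[r + 1L]] <- rbind(t1, t2)
  }
  faces <- do.call(rbind, faces)

  # enforce outward-facing normals
  e1 <- nodes[faces[, 2], ] - nodes[faces[, 1], ]
  e2 <- nodes[faces[, 3], ] - nodes[faces[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (nodes[faces[, 1], ] + nodes[faces[, 2], ] + nodes[faces[, 3], ]) / 3
  flip <- nrm[, 2] * cen[, 2] + nrm[, 3] * cen[, 3] < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]

  # unique edges and the faces flanking them
  ek <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ea <- pmin(ek[, 1], ek[, 2]); eb <- pmax(ek[, 1], ek[, 2])
  key <- paste(ea, eb)
  fidx <- rep(seq_len(nrow(faces)), times = 3)
  first <- !duplicated(key)
  edges <- cbind(ea[first], eb[first])
  edge_key <- key[first]
  by_edge <- split(fidx, key)[edge_key]

  # hinges: interior edges (exactly two flanking faces) with opposite nodes
  two <- lengths(by_edge) == 2
  if (!all(lengths(by_edge) %in% c(1L, 2L)))
    stop("mesh construction error: edge shared by more than two faces")
  f12 <- do.call(rbind, by_edge[two])
  hedge <- edges[two, , drop = FALSE]
  opp <- function(fr) rowSums(matrix(faces[fr, ], ncol = 3)) - hedge[, 1] - hedge[, 2]
  hinges <- cbind(hedge, opp(f12[, 1]), opp(f12[, 2]))

  elen <- sqrt(rowSums((nodes[edges[, 1], ] - nodes[edges[, 2], ])^2))
  tri_area <- function(f) {
    a <- nodes[faces[f, 2], , drop = FALSE] - nodes[faces[f, 1], , drop = FALSE]
    b <- nodes[faces[f, 3], , drop = FALSE] - nodes[faces[f, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  hinge_w <- elen[two] / (tri_area(f12[, 1]) + tri_area(f12[, 2]))
  hinge_theta0 <- cpp_dihedrals(nodes, hinges - 1L)

  # edge families: actin = circumferential bonds of the MPS rings
  ring_of <- function(id) (id - 1L) %/% n_c
  circumferential <- ring_of(edges[, 1]) == ring_of(edges[, 2])
  x_max <- (n_rings - 1L) * l_0
  actin_rings <- unique(pmin(
    as.integer(round((0:floor(x_max / ring_spacing)) * ring_spacing / l_0)),
    n_rings - 1L))
  is_actin <- circumferential & (ring_of(edges[, 1]) %in% actin_rings)

  A0 <- sum(tri_area(seq_len(nrow(faces))))
  pinned <- ring_of(seq_len(nrow(nodes))) %in% c(0L, n_rings - 1L)

  structure(list(
    nodes = nodes, faces = faces, edges = edges, edge_rest = elen,
    edge_type = ifelse(is_actin, "actin", "spectrin"),
    hinges = hinges, hinge_w = hinge_w, hinge_theta0 = hinge_theta0,
    A0 = A0, pinned = pinned, r_0a = r_0a, L = L, l_0 = l_0, l_a = l_a,
    ring_spacing = ring_spacing, n_c = n_c, n_rings = n_rings,
    actin_rings = actin_rings
  ), class = "axon_mesh")
}

#' @export
print.axon_mesh <- function(x, ...) {
  cat(sprintf(paste0("<axon_mesh> %d nodes (%d rings x %d), %d faces, %d edges",
                     " (%d actin, %d spectrin), %d actin rings\n"),
              nrow(x$nodes), x$n_rings, x$n_c, nrow(x$faces), nrow(x$edges),
              sum(x$edge_type == "actin"), sum(x$edge_type == "spectrin"),
              length(x$actin_rings)))
  cat(sprintf("  r_0a = %.3g nm, L = %.3g um, A0 = %.4g um^2\n",
              x$r_0a * 1e9, x$L * 1e6, x$A0 * 1e12))
  invisible(x)
}

#' Forces on membrane nodes
#'
#' The three internal force contributions on the membrane-MPS composite, each
#' a V x 3 matrix in newtons:
#'
#' * `membrane_bending_forces()`: hinge bending.  Each interior edge with its
#'   two flanking opposite nodes carries the energy
#'   `E = k_b_mem * (e/A) * (1 - cos(theta - theta0))`, with `e/A` the
#'   edge-length-to-flanking-area ratio frozen at the reference geometry and
#'   `theta0` the reference dihedral; forces are the exact negative gradient.
#' * `area_elasticity_forces()`: global area constraint
#'   `U = 1/2 k_ae A0 (A/A0 - 1)^2`; the current area is attached as
#'   attribute `"area"`.
#' * `cytoskeleton_forces()`: Hookean spectrin and actin edge springs at their
#'   recorded rest lengths.
#'
#' @param mesh an [build_axon_mesh()] mesh (possibly with displaced nodes).
#' @param config a [sim_config()] supplying `k_b_mem`, `k_ae`,
#'   `k_s_spectrin`, `k_a_actin`.
#' @return A V x 3 force matrix (N).
#' @name membrane_forces
NULL

#' @rdname membrane_forces
#' @export
membrane_bending_forces <- function(mesh, config) {
  cpp_membrane_bend_forces(mesh$nodes, mesh$hinges - 1L, mesh$hinge_w,
                           mesh$hinge_theta0, config$k_b_mem)
}

#' @rdname membrane_forces
#' @export
area_elasticity_forces <- function(mesh, config) {
  res <- cpp_area_forces(mesh$nodes, mesh$faces - 1L, mesh$A0, config$k_ae)
  structure(res$forces, area = res$area)
}

#' @rdname membrane_forces
#' @export
cytoskeleton_forces <- function(mesh, config) {
  kvec <- ifelse(mesh$edge_type == "actin", config$k_a_actin, config$k_s_spectrin)
  cpp_edge_forces(mesh$nodes, mesh$edges - 1L, mesh$edge_rest, kvec)
}

#' Advance membrane nodes by one overdamped forward-Euler step
#'
#' In `"deformable"` mode each unpinned node moves by `F / gamma_a * dt`
#' (terminal rings stay pinned); in `"fixed"` mode node positions are
#' unchanged regardless of the forces, while the WCA reaction on mitochondria
#' still applies.
#'
#' @param mesh an [build_axon_mesh()] mesh.
#' @param forces V x 3 total node force matrix (N).
#' @param config a [sim_config()]; `config$mode` selects fixed/deformable.
#' @param dt timestep (s).
#' @return The updated mesh.
#' @export
step_axon <- function(mesh, forces, config, dt) {
  if (!is.numeric(dt) || dt <= 0)
    stop("configuration error: dt must be positive")
  if (dt * config$v_0 / config$r_0a > dt_stability_bound(config))
    stop("configuration error: dt exceeds the forward-Euler stability bound")
  if (config$mode == "fixed") return(mesh)
  free <- !mesh$pinned
  mesh$nodes[free, ] <- mesh$nodes[free, ] + forces[free, ] / config$gamma_a * dt
  mesh
}
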