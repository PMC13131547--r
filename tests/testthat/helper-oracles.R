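# Numerical-gradient oracle: central finite differences of a scalar energy
# over an n x 3 coordinate matrix.
num_grad <- function(energy, X, eps) {
  g <- X * 0
  for (i in seq_len(nrow(X))) {
    for (j in 1:3) {
      Xp <- X; Xm <- X
      Xp[i, j] <- X[i, j] + eps
      Xm[i, j] <- X[i, j] - eps
      g[i, j] <- (energy(Xp) - energy(Xm)) / (2 * eps)
    }
  }
  g
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(max(abs(want)), 1e-300)
}

# A straight chain of n beads along `axis`, consecutive centres `spacing`
# apart, starting at `origin`.
straight_chain <- function(n, spacing = 250e-9, origin = c(0, 0, 0),
                           axis = c(1, 0, 0), polarity = 1L, chain_id = 1L) {
  axis <- axis / sqrt(sum(axis^2))
  pos <- t(sapply(seq_len(n) - 1, function(k) origin + k * spacing * axis))
  if (n == 1) pos <- matrix(origin, 1, 3)
  mito_state(pos, rep(chain_id, n), polarity)
}

# Random 3D rotation matrix.
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

rotate_state <- function(state, R) {
  out <- state
  out$pos <- state$pos %*% t(R)
  out
}

# Small, fast tube mesh shared across membrane tests.
small_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_axon_mesh(500e-9, 0.4e-6, l_0 = 100e-9, l_a = 200e-9)
    cache
  }
})

# The same mesh with randomly perturbed nodes (fixed seed).
perturbed_mesh <- function(sd = 5e-9, seed = 42) {
  mesh <- small_mesh()
  set.seed(seed)
  mesh$nodes <- mesh$nodes + matrix(rnorm(length(mesh$nodes), sd = sd),
                                    nrow(mesh$nodes), 3)
  mesh
}

# Energies behind each membrane kernel, for the FD oracles.
mesh_bend_energy <- function(mesh, nodes, k_b_mem) {
  th <- mitojam:::cpp_dihedrals(nodes, mesh$hinges - 1L)
  sum(k_b_mem * mesh$hinge_w * (1 - cos(th - mesh$hinge_theta0)))
}
mesh_area_energy <- function(mesh, nodes, k_ae) {
  a <- nodes[mesh$faces[, 2], ] - nodes[mesh$faces[, 1], ]
  b <- nodes[mesh$faces[, 3], ] - nodes[mesh$faces[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  A <- sum(0.5 * sqrt(rowSums(cr^2)))
  0.5 * k_ae * mesh$A0 * (A / mesh$A0 - 1)^2
}
mesh_spring_energy <- function(mesh, nodes, k_s, k_a) {
  d <- sqrt(rowSums((nodes[mesh$edges[, 1], ] - nodes[mesh$edges[, 2], ])^2))
  kv <- ifelse(mesh$edge_type == "actin", k_a, k_s)
  sum(0.5 * kv * (d - mesh$edge_rest)^2)
}
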