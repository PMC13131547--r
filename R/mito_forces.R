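#' Forces on mitochondrial beads
#'
#' The four force contributions acting on each mitochondrial bead, each
#' returned as an n x 3 matrix in newtons (rows aligned with the beads of
#' `state`):
#'
#' * `mito_bending_forces()`: negative gradient of the quadratic bending
#'   energy `U_b = k_b_mito * theta^2 / (8 r_m)` of each interior bead triple,
#'   where theta is the angle between consecutive bond tangents (0 for a
#'   straight chain).  Chains shorter than 3 beads contribute nothing.
#' * `mito_spring_forces()`: Hookean bonds between consecutive beads of a
#'   chain, rest length one bead diameter `2 r_m`.
#' * `mito_steric_forces()`: repulsive Hookean contact of range `2 r_m`
#'   between every non-bonded bead pair (within and across chains); pairs at
#'   or beyond `2 r_m` contribute exactly zero.
#' * `wca_forces()`: purely repulsive WCA contact (epsilon `phi_0`, sigma
#'   `r_m`, cutoff `2^(1/6) r_m`) between beads and membrane nodes; the node
#'   receives the exact opposite of the bead force.
#'
#' The steric and WCA sums run over a cell list with cell size equal to the
#' interaction cutoff; `method = "brute"` forces the all-pairs double loop
#' (identical result, used as the oracle in the tests).
#'
#' @param state a [mito_state()].
#' @param config a [sim_config()] supplying the mechanical constants.
#' @param method `"cell"` (default) or `"brute"` neighbour search.
#' @return An n x 3 force matrix (N); `wca_forces()` returns a list with
#'   elements `bead_forces` and `node_forces`.
#' @name mito_forces
NULL

check_bond_geometry <- function(state, pairs) {
  if (nrow(pairs) == 0) return(invisible())
  d <- state$pos[pairs[, 1], , drop = FALSE] - state$pos[pairs[, 2], , drop = FALSE]
  if (any(rowSums(d^2) == 0))
    stop("degenerate geometry: coincident consecutive beads in a chain")
}

#' @rdname mito_forces
#' @export
mito_bending_forces <- function(state, config) {
  tr <- chain_triples(state)
  check_bond_geometry(state, chain_bonds(state))
  cpp_bend_forces(state$pos, tr - 1L, config$k_b_mito, config$r_m)
}

#' @rdname mito_forces
#' @export
mito_spring_forces <- function(state, config) {
  b <- chain_bonds(state)
  check_bond_geometry(state, b)
  cpp_spring_forces(state$pos, b - 1L, config$k_s_mito, config$r_m)
}

#' @rdname mito_forces
#' @export
mito_steric_forces <- function(state, config, method = c("cell", "brute")) {
  method <- match.arg(method)
  bc <- bead_chain_index(state)
  cpp_steric_forces(state$pos, bc$chain, bc$ord, config$k_m_steric, config$r_m,
                    method == "cell")
}

#' @rdname mito_forces
#' @param mesh an [build_axon_mesh()] mesh, or an m x 3 matrix of node
#'   positions (m).
#' @export
wca_forces <- function(state, mesh, config, method = c("cell", "brute")) {
  method <- match.arg(method)
  nodes <- if (inherits(mesh, "axon_mesh")) mesh$nodes else as.matrix(mesh)
  res <- cpp_wca_forces(state$pos, nodes, config$phi_0, config$r_m,
                        config$wca_floor_frac, method == "cell")
  if (res$n_clamped > 0)
    warning(sprintf(paste0("%d bead-node pair(s) closer than %.2g r_m; ",
                           "WCA force clamped at the floor distance"),
                    res$n_clamped, config$wca_floor_frac))
  res[c("bead_forces", "node_forces")]
}

#' Advance mitochondria by one overdamped forward-Euler step
#'
#' Each bead moves by `(F / gamma_m + v n) * dt` with `n = +x` for
#' anterograde and `-x` for retrograde chains and `v` the corresponding
#' propulsion speed.  The instantaneous velocities (the bracketed rates) are
#' attached as attribute `"velocities"` for the observables.
#'
#' @param state a [mito_state()].
#' @param forces n x 3 total force matrix (N).
#' @param config a [sim_config()].
#' @param dt timestep (s); must satisfy the stability bound
#'   [dt_stability_bound()].
#' @return The advanced [mito_state()].
#' @export
step_mitochondria <- function(state, forces, config, dt) {
  if (!is.numeric(dt) || dt <= 0)
    stop("configuration error: dt must be positive")
  if (dt * config$v_0 / config$r_0a > dt_stability_bound(config))
    stop("configuration error: dt exceeds the forward-Euler stability bound")
  v_prop <- ifelse(state$polarity > 0, config$v_a, -config$v_r)
  vel <- forces / config$gamma_m
  vel[, 1] <- vel[, 1] + v_prop
  out <- state
  out$pos <- state$pos + vel * dt
  attr(out, "velocities") <- vel
  out
}
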