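#' Stochastic fission and fusion
#'
#' One lifecycle step edits chain ids and connectivity only; bead positions,
#' particle ids and the bead count are untouched.
#'
#' `fission_step()`: each chain of length >= 2 splits this step with
#' probability `min(k_fission * dt, 1)` at a uniformly random internal bond.
#' The tail-side fragment receives a fresh, never-reused chain id; both
#' fragments inherit the parent polarity.
#'
#' `fusion_step()`: candidate pairs are chain termini (beads with at most one
#' intra-chain neighbour) from distinct chains.  A pair fuses iff (a) an
#' independent uniform draw succeeds with probability `min(k_fusion * dt, 1)`,
#' (b) the termini are within `r_fusion`, and (c) the chain orientations
#' (end-to-end unit vector from first to last bead; the polarity axis for
#' single beads) differ by at most `theta_cutoff` degrees.  Candidate pairs
#' are processed in random order and a terminus fuses at most once per step.
#' Same-polarity chains keep their polarity; a mixed pair picks the fused
#' polarity uniformly at random.
#'
#' @param state a [mito_state()].
#' @param config a [sim_config()] supplying `k_fission`, `k_fusion`,
#'   `r_fusion` and `theta_cutoff`.
#' @param dt timestep (s).
#' @return The updated [mito_state()].
#' @name lifecycle
#' @examples
#' set.seed(1)
#' s <- mito_state(cbind(2 * 125e-9 * (0:4), 0, 0), rep(1L, 5), 1L)
#' cfg <- sim_config(k_fission = 10)
#' table(fission_step(s, cfg, dt = 1)$chain_id)  # split into two fragments
NULL

next_chain_id <- function(state) {
  if (n_beads(state) == 0) 1L else max(state$chain_id) + 1L
}

lifecycle_call <- function(state, pfis, pfus, rfus, cos_cut) {
  res <- cpp_lifecycle_step(state$pos, state$particle_id, state$chain_id,
                            state$polarity, pfis, pfus, rfus, cos_cut,
                            next_chain_id(state))
  mito_state(res$pos, res$chain_id, res$polarity, res$particle_id)
}

#' @rdname lifecycle
#' @export
fission_step <- function(state, config, dt) {
  stopifnot(dt > 0)
  p <- min(config$k_fission * dt, 1)
  if (p <= 0 || n_beads(state) == 0) return(state)
  lifecycle_call(state, p, 0, config$r_fusion, cos(config$theta_cutoff * pi / 180))
}

#' @rdname lifecycle
#' @export
fusion_step <- function(state, config, dt) {
  stopifnot(dt > 0)
  p <- min(config$k_fusion * dt, 1)
  if (p <= 0 || n_beads(state) == 0) return(state)
  lifecycle_call(state, 0, p, config$r_fusion, cos(config$theta_cutoff * pi / 180))
}
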