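#' Inject one mitochondrial chain at an axon end
#'
#' Anterograde chains are generated with their rear bead at `x = 0` and
#' subsequent beads at `+2 r_m` increments; retrograde chains mirror this from
#' `x = L` with `-2 r_m` increments.  All beads of a chain share a `(y, z)`
#' position drawn uniformly from the disc of radius `r_0a - r_m` (so a fresh
#' chain never overlaps the membrane).  New beads receive fresh particle ids
#' and one fresh chain id.
#'
#' @param state a [mito_state()] to extend.
#' @param config a [sim_config()].
#' @param direction `"anterograde"` or `"retrograde"`.
#' @return The extended [mito_state()].
#' @export
inject_mitochondria <- function(state, config,
                                direction = c("anterograde", "retrograde")) {
  direction <- match.arg(direction)
  n <- config$n_chain
  if (n * 2 * config$r_m > config$L)
    stop("configuration error: injected chain longer than the axon")
  u <- runif(2)
  rr <- (config$r_0a - config$r_m) * sqrt(u[1])
  th <- 2 * pi * u[2]
  xs <- if (direction == "anterograde") 2 * config$r_m * (seq_len(n) - 1)
        else config$L - 2 * config$r_m * (seq_len(n) - 1)
  newpos <- cbind(xs, rr * cos(th), rr * sin(th))
  pid0 <- if (n_beads(state) == 0) 0L else max(state$particle_id)
  cid0 <- if (n_beads(state) == 0) 0L else max(state$chain_id)
  pol <- if (direction == "anterograde") 1L else -1L
  mito_state(rbind(state$pos, newpos),
             c(state$chain_id, rep(cid0 + 1L, n)),
             c(state$polarity, rep(pol, n)),
             c(state$particle_id, pid0 + seq_len(n)))
}

#' Remove mitochondria that escaped the axon
#'
#' Applies the configured escape rule (`config$removal`):
#' * `"exit"` (default): a bead is deleted once it crosses the end it travels
#'   toward (anterograde at `x > L`, retrograde at `x < 0`), shortening the
#'   chain it leaves; beads shoved backward out of the segment are retained.
#' * `"bead"`: any bead beyond either open end is deleted.
#' * `"chain"`: a chain is deleted only once every one of its beads lies
#'   beyond an open end (all `x < 0` or all `x > L`); straddling chains are
#'   retained whole.
#'
#' The number of removed beads is attached as attribute `"removed_beads"`.
#'
#' @param state a [mito_state()].
#' @param config a [sim_config()] supplying `L` and `removal`.
#' @return The pruned [mito_state()].
#' @export
remove_escaped <- function(state, config) {
  n <- n_beads(state)
  if (n == 0) return(structure(state, removed_beads = 0L))
  xs <- state$pos[, 1]
  if (config$removal == "exit") {
    keep_bead <- !((state$polarity > 0 & xs > config$L) |
                     (state$polarity < 0 & xs < 0))
  } else if (config$removal == "bead") {
    keep_bead <- xs >= 0 & xs <= config$L
  } else {
    ct <- chain_table(state)
    keep_bead <- rep(TRUE, n)
    for (i in seq_len(nrow(ct))) {
      idx <- ct$start[i]:(ct$start[i] + ct$length[i] - 1L)
      if (all(xs[idx] < 0) || all(xs[idx] > config$L)) keep_bead[idx] <- FALSE
    }
  }
  out <- mito_state(state$pos[keep_bead, , drop = FALSE],
                    state$chain_id[keep_bead], state$polarity[keep_bead],
                    state$particle_id[keep_bead])
  structure(out, removed_beads = as.integer(sum(!keep_bead)))
}

# Mesh in the form the C++ core consumes, rescaled by `scale` (1 for SI,
# 1/r_0a for dimensionless runs).  The hinge weight e/A has units 1/length.
mesh_for_core <- function(mesh, config, nd, scale) {
  k_s <- if (scale == 1) config$k_s_spectrin else nd$k_s_spectrin
  k_a <- if (scale == 1) config$k_a_actin else nd$k_a_actin
  list(nodes = mesh$nodes * scale,
       faces = mesh$faces - 1L,
       hinges = mesh$hinges - 1L,
       hinge_w = mesh$hinge_w / scale,
       hinge_theta0 = mesh$hinge_theta0,
       edges = mesh$edges - 1L,
       edge_rest = mesh$edge_rest * scale,
       edge_k = ifelse(mesh$edge_type == "actin", k_a, k_s),
       A0 = mesh$A0 * scale^2,
       pinned = mesh$pinned,
       r0a = mesh$r_0a * scale)
}

#' Run a full transport simulation
#'
#' Executes the complete protocol: the tube is built, `n_initial_pairs`
#' anterograde and retrograde chains are generated at the two ends, and every
#' `injection_interval_steps` timesteps one further chain of each direction is
#' injected until the cumulative injected bead count reaches the density
#' target [density_to_bead_count()].  Each step computes all forces, applies
#' fission/fusion, advances mitochondria (and, in deformable mode, membrane
#' nodes) by forward Euler, and deletes chains that escaped the open ends.
#' Observables are recorded every `snapshot_stride` steps.
#'
#' The run is seeded from `config$seed`; identical configurations give
#' bit-identical trajectories.  The engine aborts with a diagnostic if any
#' per-step displacement exceeds the bead radius (instability) or a membrane
#' face inverts.
#'
#' @param config a [sim_config()].
#' @param record_frames keep full bead snapshots (memory-hungry for long
#'   runs); the observable series is always recorded.
#' @param units `"dimensionless"` (default) integrates in internal units;
#'   `"si"` integrates the identical dynamics in SI units (used to verify the
#'   nondimensionalization).
#' @param initial_state optional [mito_state()] (SI positions) replacing the
#'   default symmetric initialisation, e.g. a single chain for controlled
#'   transit experiments.  Beads present count toward the injection target.
#' @param verbose print a progress line every 1000 steps.
#' @return A `mito_trajectory`: list with `series` (data.frame of time (s),
#'   `mean_abs_vx` (m/s), `nematic_Sx`, `shape_factor`, `mean_chain_length`,
#'   `max_radial_dilation`, `max_node_speed`, bead/chain counts), `frames`
#'   (list of snapshots), `t_inject_end` (s), bead bookkeeping, the final
#'   state and the mesh.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(phi_fraction = 0.3, t_star = 5, seed = 7)
#' traj <- run_simulation(cfg, record_frames = FALSE)
#' head(traj$series)
#' }
run_simulation <- function(config, record_frames = TRUE,
                           units = c("dimensionless", "si"),
                           initial_state = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  units <- match.arg(units)
  validate_sim_config(config)
  set.seed(config$seed)

  mesh <- build_axon_mesh(config$r_0a, config$L, config$l_0, config$l_a,
                          config$ring_spacing)
  target <- density_to_bead_count(config$phi_fraction, config)

  if (!is.null(initial_state)) {
    stopifnot(inherits(initial_state, "mito_state"))
    state <- initial_state
  } else {
    state <- empty_mito_state()
    if (target > 0 && config$n_initial_pairs > 0) {
      for (i in seq_len(config$n_initial_pairs)) {
        state <- inject_mitochondria(state, config, "anterograde")
        state <- inject_mitochondria(state, config, "retrograde")
      }
    }
  }

  nd <- nondimensionalize(config)
  lsc <- nd$scales$length; tsc <- nd$scales$time; vsc <- nd$scales$velocity
  if (units == "dimensionless") {
    par <- list(r_m = nd$r_m, k_s_mito = nd$k_s_mito, k_b_mito = nd$k_b_mito,
                k_m_steric = nd$k_m_steric, phi_0 = nd$phi_0, gamma_m = 1,
                gamma_a = nd$gamma_a, v_a = nd$v_a, v_r = nd$v_r,
                k_b_mem = nd$k_b_mem, k_ae = nd$k_ae, L = nd$L,
                k_fission = nd$k_fission, k_fusion = nd$k_fusion,
                r_fusion = nd$r_fusion,
                cos_theta_cutoff = cos(config$theta_cutoff * pi / 180),
                wca_floor_frac = config$wca_floor_frac)
    dt <- config$dt_star
    scale <- 1 / lsc
    out_len <- lsc; out_time <- tsc; out_vel <- vsc
  } else {
    par <- list(r_m = config$r_m, k_s_mito = config$k_s_mito,
                k_b_mito = config$k_b_mito, k_m_steric = config$k_m_steric,
                phi_0 = config$phi_0, gamma_m = config$gamma_m,
                gamma_a = config$gamma_a, v_a = config$v_a, v_r = config$v_r,
                k_b_mem = config$k_b_mem, k_ae = config$k_ae, L = config$L,
                k_fission = config$k_fission, k_fusion = config$k_fusion,
                r_fusion = config$r_fusion,
                cos_theta_cutoff = cos(config$theta_cutoff * pi / 180),
                wca_floor_frac = config$wca_floor_frac)
    dt <- config$dt_star * tsc
    scale <- 1
    out_len <- 1; out_time <- 1; out_vel <- 1
  }

  nsteps <- as.integer(round(config$t_star / config$dt_star))
  ctrl <- list(dt = dt, nsteps = nsteps, stride = config$snapshot_stride,
               fixed_mode = (config$mode == "fixed"),
               record_frames = record_frames,
               interval = config$injection_interval_steps,
               n_chain = config$n_chain, target = as.double(target),
               next_pid = if (n_beads(state) == 0) 1L else max(state$particle_id) + 1L,
               next_cid = if (n_beads(state) == 0) 1L else max(state$chain_id) + 1L,
               injected = as.double(n_beads(state)),
               inject_radius = (config$r_0a - config$r_m) * scale,
               removal_mode = match(config$removal, c("exit", "bead", "chain")) - 1L,
               progress = if (isTRUE(verbose)) 1000L else 0L)

  res <- cpp_run_core(state$pos * scale, state$particle_id, state$chain_id,
                      state$polarity, mesh_for_core(mesh, config, nd, scale),
                      par, ctrl)

  if (res$status != "ok")
    stop(sprintf(paste0("simulation aborted (%s) at step %d (t = %.4g s); ",
                        "max per-step displacement %.3g r_m"),
                 res$status, res$stop_step, res$stop_step * dt * out_time / 1,
                 res$max_disp / par$r_m))

  series <- res$series
  series$time <- series$time * out_time
  series$mean_abs_vx <- series$mean_abs_vx * out_vel
  series$max_node_speed <- series$max_node_speed * out_vel

  frames <- lapply(res$frames, function(fr) {
    st <- mito_state(fr$pos * out_len, fr$chain_id, fr$polarity, fr$particle_id)
    structure(list(time = fr$time * out_time, state = st,
                   velocities = fr$vel * out_vel,
                   nodes = if (!is.null(fr$nodes)) fr$nodes * out_len else NULL),
              class = "trajectory_frame")
  })

  final_state <- mito_state(res$pos * out_len, res$chain_id, res$polarity,
                            res$particle_id)
  t_end <- res$t_inject_end
  if (is.na(t_end))
    warning("injection did not complete within the run; relief time undefined")

  structure(list(
    config = config, series = series, frames = frames,
    t_inject_end = if (is.na(t_end)) NA_real_ else t_end * out_time,
    target_beads = target, injected = res$injected, removed = res$removed,
    final_state = final_state, final_nodes = res$nodes * out_len,
    mesh = mesh, mode = config$mode, units = units,
    n_clamped = res$n_clamped, max_disp = res$max_disp,
    max_folded_hinges = res$max_folded_hinges
  ), class = "mito_trajectory")
}

#' @export
print.mito_trajectory <- function(x, ...) {
  cat(sprintf("<mito_trajectory> %s axon, phi = %.2g phi_max, N_chain = %d\n",
              x$mode, x$config$phi_fraction, x$config$n_chain))
  cat(sprintf("  %d series records over %.3g s; %d frames; injected %d beads, removed %d\n",
              nrow(x$series), max(x$series$time), length(x$frames),
              as.integer(x$injected), as.integer(x$removed)))
  tau <- tryCatch(relief_time(x), error = function(e) NA_real_)
  cat(sprintf("  injection complete at t = %.3g s; relief time %s\n",
              x$t_inject_end,
              if (is.na(tau)) "not reached" else sprintf("%.3g s", tau)))
  invisible(x)
}
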