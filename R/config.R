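#' Maximum filling fraction of hexagonally close-packed spheres
#'
#' The packing constant used to convert a relative mitochondrial density
#' into an absolute bead count: \eqn{\phi_{max} = \pi/(3\sqrt{2}) \approx
#' 0.7405}.
#'
#' @return A single number.
#' @export
#' @examples
#' phi_max_hcp()
phi_max_hcp <- function() pi / (3 * sqrt(2))

# Baseline parameter set, SI units throughout (m, s, N, J, kg).
default_config_fields <- function() {
  list(
    # geometry
    r_0a = 500e-9,          # initial axon radius (m)
    L = 3.8e-6,             # axon segment length (m)
    l_0 = 38e-9,            # lattice (spectrin) rest length (m)
    l_a = 65e-9,            # actin rest length (m)
    ring_spacing = 180e-9,  # actin ring period of the MPS (m)
    r_m = 125e-9,           # mitochondrial bead radius (m)
    # motility
    v_0 = 0.5e-6,           # average mitochondrial speed (m/s)
    v_a = 0.5e-6,           # anterograde propulsion speed (m/s)
    v_r = 0.5e-6,           # retrograde propulsion speed (m/s)
    # population
    phi_fraction = 0.9,     # density as a multiple of phi_max_hcp()
    n_chain = 5L,           # beads per injected mitochondrion
    # drag
    gamma_a = 1,            # membrane node drag (kg/s)
    gamma_m = 1,            # mitochondrial bead drag (kg/s)
    # membrane / MPS mechanics
    k_b_mem = 5e-19,        # membrane bending rigidity (J)
    k_ae = 1e-15,           # area elasticity modulus (J)
    k_s_spectrin = 2.06e-4, # spectrin spring coefficient (N/m)
    k_a_actin = 0.26,       # actin spring coefficient (N/m)
    # mitochondrial mechanics
    k_m_steric = 40,        # mito-mito steric spring coefficient (N/m)
    phi_0 = 5e-15,          # mito-membrane WCA strength (J)
    k_b_mito = 1e-19,       # mitochondrial bending rigidity (N m^2)
    k_s_mito = 100,         # intra-chain spring coefficient (N/m)
    # lifecycle
    k_fission = 0,          # fission rate (1/s); 0 = static chains
    k_fusion = 0,           # fusion rate (1/s)
    r_fusion = NULL,        # fusion distance threshold (m); default 1.1 * 2 r_m
    theta_cutoff = 30,      # fusion orientation threshold (degrees)
    # run controls
    dt_star = 1e-3,         # dimensionless timestep (units of r_0a / v_0)
    t_star = 60,            # dimensionless duration
    seed = 1L,
    mode = "fixed",         # "fixed" or "deformable" membrane
    injection_interval_steps = NULL,  # default 10 * n_chain
    snapshot_stride = 100L,
    n_initial_pairs = 2L,   # chains of each direction present at t = 0
    removal = "exit",       # escape removal: "exit" (beads leaving through the
                            # end they travel toward, one by one, shortening
                            # their chain), "bead" (either end, per bead) or
                            # "chain" (whole chain once every bead is outside)
    wca_floor_frac = 0.1    # WCA clamp floor as a fraction of r_m
  )
}

#' Simulation configuration
#'
#' Builds and validates the full parameter set of a run: axon and mesh
#' geometry, mitochondrial mechanics, lifecycle rates, and run controls.
#' All physical quantities are SI; the engine integrates in dimensionless
#' units (see [nondimensionalize()]).  Defaults are the baseline axonal
#' parameter set (axon radius 500 nm, bead radius 125 nm, propulsion
#' 0.5 um/s, ...).
#'
#' @param ... named overrides of the default fields; unknown names are an
#'   error.
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(phi_fraction = 0.3, n_chain = 5, seed = 42)
#' cfg$r_fusion   # defaults to 1.1 * 2 * r_m
sim_config <- function(...) {
  defaults <- default_config_fields()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown configuration key(s): ",
           paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "))
    defaults[names(over)] <- over
  }
  cfg <- defaults
  if (is.null(cfg$r_fusion)) cfg$r_fusion <- 1.1 * 2 * cfg$r_m
  if (is.null(cfg$injection_interval_steps))
    cfg$injection_interval_steps <- 10L * as.integer(cfg$n_chain)
  cfg$n_chain <- as.integer(cfg$n_chain)
  cfg$seed <- as.integer(cfg$seed)
  cfg$snapshot_stride <- as.integer(cfg$snapshot_stride)
  cfg$injection_interval_steps <- as.integer(cfg$injection_interval_steps)
  cfg$n_initial_pairs <- as.integer(cfg$n_initial_pairs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid configuration: `", field, "` ", msg, call. = FALSE)
  }
  pos <- c("r_0a", "L", "l_0", "l_a", "ring_spacing", "r_m", "v_0", "v_a", "v_r",
           "gamma_a", "gamma_m", "k_b_mem", "k_ae", "k_s_spectrin", "k_a_actin",
           "k_m_steric", "phi_0", "k_b_mito", "k_s_mito", "dt_star", "t_star")
  for (f in pos) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
                     f, "must be a single positive number")
  for (f in c("k_fission", "k_fusion"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
        f, "must be a non-negative rate (1/s)")
  chk(cfg$phi_fraction > 0 && cfg$phi_fraction <= 1, "phi_fraction",
      "must lie in (0, 1] (as a multiple of phi_max)")
  chk(cfg$n_chain >= 1, "n_chain", "must be >= 1")
  chk(cfg$L > cfg$n_chain * 2 * cfg$r_m, "L",
      "must exceed the injected chain length n_chain * 2 r_m")
  chk(cfg$r_fusion > 2 * cfg$r_m, "r_fusion", "must exceed the bead diameter 2 r_m")
  chk(cfg$theta_cutoff > 0 && cfg$theta_cutoff < 90, "theta_cutoff",
      "must lie in (0, 90) degrees")
  chk(cfg$mode %in% c("fixed", "deformable"), "mode",
      'must be "fixed" or "deformable"')
  chk(cfg$removal %in% c("exit", "bead", "chain"), "removal",
      'must be "exit", "bead" or "chain"')
  chk(cfg$injection_interval_steps >= 1, "injection_interval_steps", "must be >= 1")
  chk(cfg$snapshot_stride >= 1, "snapshot_stride", "must be >= 1")
  chk(cfg$n_initial_pairs >= 0, "n_initial_pairs", "must be >= 0")
  chk(cfg$wca_floor_frac > 0 && cfg$wca_floor_frac < 1, "wca_floor_frac",
      "must lie in (0, 1)")
  bound <- dt_stability_bound(cfg)
  chk(cfg$dt_star <= bound, "dt_star",
      sprintf("exceeds the forward-Euler stability bound 2/k*_max = %.3g", bound))
  invisible(cfg)
}

#' Forward-Euler stability bound on the dimensionless timestep
#'
#' The stiffest dimensionless spring constant (per its drag) sets the linear
#' stability limit `dt* <= 2 / k*_max`.
#'
#' @param config a [sim_config()].
#' @return The maximum admissible `dt_star`.
#' @export
dt_stability_bound <- function(config) {
  k_mito <- max(config$k_s_mito, config$k_m_steric) *
    config$r_0a / (config$gamma_m * config$v_0)
  k_mem <- max(config$k_s_spectrin, config$k_a_actin) *
    config$r_0a / (config$gamma_a * config$v_0)
  2 / max(k_mito, k_mem)
}

#' Nondimensionalize a configuration
#'
#' Rescales all parameters to the internal simulation units: lengths by the
#' initial axon radius `r_0a`, times by `r_0a / v_0`, velocities by `v_0`,
#' forces by `gamma_m * v_0`, energies by `gamma_m * v_0 * r_0a`, and bending
#' rigidities (force x length^2) by `gamma_m * v_0 * r_0a^2`.
#' [redimensionalize()] inverts the map exactly.
#'
#' @param config a [sim_config()].
#' @return A list of dimensionless parameters plus a `scales` element.
#' @export
#' @examples
#' nd <- nondimensionalize(sim_config())
#' nd$r_m    # 0.25: bead radius in units of the axon radius
#' nd$v_a    # 1
nondimensionalize <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ls <- config$r_0a
  vs <- config$v_0
  ts <- ls / vs
  fs <- config$gamma_m * vs        # force scale
  es <- fs * ls                    # energy scale
  list(
    r_0a = 1,
    L = config$L / ls, l_0 = config$l_0 / ls, l_a = config$l_a / ls,
    ring_spacing = config$ring_spacing / ls, r_m = config$r_m / ls,
    r_fusion = config$r_fusion / ls,
    v_a = config$v_a / vs, v_r = config$v_r / vs,
    gamma_m = 1, gamma_a = config$gamma_a / config$gamma_m,
    k_s_mito = config$k_s_mito * ls / fs,
    k_m_steric = config$k_m_steric * ls / fs,
    k_s_spectrin = config$k_s_spectrin * ls / fs,
    k_a_actin = config$k_a_actin * ls / fs,
    phi_0 = config$phi_0 / es,
    k_ae = config$k_ae / es,
    k_b_mem = config$k_b_mem / es,
    k_b_mito = config$k_b_mito / (es * ls),
    k_fission = config$k_fission * ts,
    k_fusion = config$k_fusion * ts,
    theta_cutoff = config$theta_cutoff,
    dt = config$dt_star, duration = config$t_star,
    scales = list(length = ls, time = ts, velocity = vs, force = fs, energy = es)
  )
}

#' @rdname nondimensionalize
#' @param nd a dimensionless parameter set from [nondimensionalize()].
#' @export
redimensionalize <- function(nd) {
  s <- nd$scales
  list(
    r_0a = s$length, L = nd$L * s$length, l_0 = nd$l_0 * s$length,
    l_a = nd$l_a * s$length, ring_spacing = nd$ring_spacing * s$length,
    r_m = nd$r_m * s$length, r_fusion = nd$r_fusion * s$length,
    v_a = nd$v_a * s$velocity, v_r = nd$v_r * s$velocity, v_0 = s$velocity,
    gamma_m = s$force / s$velocity,
    gamma_a = nd$gamma_a * s$force / s$velocity,
    k_s_mito = nd$k_s_mito * s$force / s$length,
    k_m_steric = nd$k_m_steric * s$force / s$length,
    k_s_spectrin = nd$k_s_spectrin * s$force / s$length,
    k_a_actin = nd$k_a_actin * s$force / s$length,
    phi_0 = nd$phi_0 * s$energy, k_ae = nd$k_ae * s$energy,
    k_b_mem = nd$k_b_mem * s$energy,
    k_b_mito = nd$k_b_mito * s$energy * s$length,
    k_fission = nd$k_fission / s$time, k_fusion = nd$k_fusion / s$time,
    theta_cutoff = nd$theta_cutoff
  )
}

#' Convert a relative density to an absolute bead count
#'
#' The number of mitochondrial beads occupying the axon at density
#' `phi = phi_fraction * phi_max` is `floor(phi * V_axon / V_bead)` with
#' `V_axon = pi r_0a^2 L`, `V_bead = (4/3) pi r_m^3` and `phi_max` the
#' hexagonal close-packing fraction.
#'
#' @param phi_fraction density as a multiple of [phi_max_hcp()], in (0, 1].
#' @param config a [sim_config()] supplying the geometry.
#' @return Integer bead count.
#' @export
#' @examples
#' cfg <- sim_config()
#' density_to_bead_count(0.3, cfg)  # 81
#' density_to_bead_count(0.9, cfg)  # 243
density_to_bead_count <- function(phi_fraction, config) {
  if (!is.numeric(phi_fraction) || length(phi_fraction) != 1 || phi_fraction <= 0)
    stop("phi_fraction must be a single positive number")
  v_axon <- pi * config$r_0a^2 * config$L
  v_bead <- 4 / 3 * pi * config$r_m^3
  as.integer(floor(phi_fraction * phi_max_hcp() * v_axon / v_bead))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  axon: L = %.3g um, r_0a = %.3g nm, mode = %s\n",
              x$L * 1e6, x$r_0a * 1e9, x$mode))
  cat(sprintf("  mitochondria: N_chain = %d, r_m = %.3g nm, phi = %.2g phi_max (%d beads)\n",
              x$n_chain, x$r_m * 1e9, x$phi_fraction,
              density_to_bead_count(x$phi_fraction, x)))
  cat(sprintf("  mechanics: k_b_mito = %.3g N m^2, k_s_mito = %.3g N/m, k_M = %.3g N/m\n",
              x$k_b_mito, x$k_s_mito, x$k_m_steric))
  cat(sprintf("  lifecycle: k_fission = %.3g /s, k_fusion = %.3g /s\n",
              x$k_fission, x$k_fusion))
  cat(sprintf("  run: dt* = %.3g, T* = %.3g, seed = %d\n", x$dt_star, x$t_star, x$seed))
  invisible(x)
}
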