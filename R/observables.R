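#' Ensemble axial speed of a frame
#'
#' Mean over all beads of the absolute x-velocity, using the instantaneous
#' equation-of-motion rates recorded with the frame (not finite differences of
#' saved positions).
#'
#' @param frame a `trajectory_frame` from [run_simulation()], or any list with
#'   a `velocities` matrix.
#' @return Speed (m/s); `NA` with a warning for an empty frame.
#' @export
ensemble_speed_x <- function(frame) {
  v <- frame$velocities
  if (is.null(v) || nrow(v) == 0) {
    warning("undefined: frame contains no beads")
    return(NA_real_)
  }
  mean(abs(v[, 1]))
}

relief_time_core <- function(time, v, v_0, after) {
  sel <- which(time >= after & !is.na(v))
  if (length(sel) == 0)
    stop("series does not cover the post-injection window")
  tt <- time[sel]
  vv <- v[sel]
  thr <- 0.95 * v_0
  if (min(vv) >= thr) return(0)
  im <- which.min(vv)
  rec <- which(vv[im:length(vv)] >= thr)
  if (length(rec) == 0)
    return(structure(NA_real_, status = "unrelieved"))
  structure(tt[im + rec[1] - 1L], status = "relieved")
}

#' Relief time of a traffic jam
#'
#' The first time, after the post-injection minimum of the ensemble axial
#' speed, at which the speed recovers to 95 percent of the propulsion speed
#' `v_0`.  The search window starts when injection completes, excluding the
#' early fluctuations caused by chain generation.  Returns 0 if the speed
#' never drops below the threshold in the window (no jam), and `NA` with
#' attribute `status = "unrelieved"` if it never recovers within the run.
#'
#' @param x a `mito_trajectory`, or a data.frame with columns `time` and
#'   `mean_abs_vx`.
#' @param v_0 propulsion speed; taken from the configuration for
#'   trajectories.
#' @param after start of the search window (s); defaults to the injection-end
#'   time for trajectories and 0 otherwise.
#' @param ... unused.
#' @return Relief time in seconds.
#' @export
relief_time <- function(x, ...) UseMethod("relief_time")

#' @rdname relief_time
#' @export
relief_time.mito_trajectory <- function(x, v_0 = x$config$v_0,
                                        after = x$t_inject_end, ...) {
  if (is.na(after))
    stop("injection did not complete; the series does not cover the jam")
  relief_time_core(x$series$time, x$series$mean_abs_vx, v_0, after)
}

#' @rdname relief_time
#' @export
relief_time.data.frame <- function(x, v_0, after = 0, ...) {
  relief_time_core(x$time, x$mean_abs_vx, v_0, after)
}

#' Nematic order parameter along the axon axis
#'
#' `S_x = <(3 cos^2 theta - 1) / 2>` averaged over all intra-chain bonds,
#' where theta is the angle between the bond vector and the x axis: 1 for
#' perfect alignment, 0 for an isotropic population, -0.5 for bonds
#' perpendicular to the axis.
#'
#' For a population of single-bead chains no bond exists and the order
#' parameter is undefined (`NA` with a warning); `singles = "polarity"`
#' substitutes each lone bead's polarity axis (contributing 1).
#'
#' @param state a [mito_state()].
#' @param singles `"undefined"` (default) or `"polarity"`.
#' @return S_x in `[-0.5, 1]`.
#' @export
nematic_order_x <- function(state, singles = c("undefined", "polarity")) {
  singles <- match.arg(singles)
  b <- chain_bonds(state)
  vals <- numeric(0)
  if (nrow(b) > 0) {
    d <- state$pos[b[, 2], , drop = FALSE] - state$pos[b[, 1], , drop = FALSE]
    c2 <- d[, 1]^2 / rowSums(d^2)
    vals <- (3 * c2 - 1) / 2
  }
  if (singles == "polarity") {
    ct <- chain_table(state)
    vals <- c(vals, rep(1, sum(ct$length == 1)))
  }
  if (length(vals) == 0) {
    warning("undefined: no intra-chain bonds (population of single beads)")
    return(NA_real_)
  }
  mean(vals)
}

#' Shape factor of the mitochondrial population
#'
#' Per chain, the sum of squared bead distances from the chain's centre of
#' mass, normalised by the squared bead diameter `(2 r_m)^2` and by the
#' squared chain length `N^2`, averaged over chains.  A straight N-bead chain
#' at rest spacing gives `(N^2 - 1) / (12 N)` -- 0.4 for N = 5; low values
#' indicate globular, collision-prone morphologies.
#'
#' @param state a [mito_state()].
#' @param r_m bead radius (m).
#' @return Dimensionless shape factor (>= 0).
#' @export
shape_factor <- function(state, r_m) {
  ct <- chain_table(state)
  if (nrow(ct) == 0) {
    warning("undefined: population is empty")
    return(NA_real_)
  }
  per_chain <- vapply(seq_len(nrow(ct)), function(i) {
    idx <- ct$start[i]:(ct$start[i] + ct$length[i] - 1L)
    p <- state$pos[idx, , drop = FALSE]
    com <- colMeans(p)
    sum(sweep(p, 2, com)^2) / (ct$length[i]^2 * (2 * r_m)^2)
  }, numeric(1))
  mean(per_chain)
}

#' Maximum radial membrane dilation
#'
#' Per frame, the largest relative radial displacement of any membrane node,
#' `max_i (sqrt(y_i^2 + z_i^2) - r_0a) / r_0a`, and its peak over time.  For a
#' fixed-axon trajectory the membrane never moves and the series is all zeros
#' (with a warning).
#'
#' @param x a `mito_trajectory`, or a list of V x 3 node-position matrices.
#' @param r_0a reference tube radius (m); taken from the configuration for
#'   trajectories.
#' @param ... unused.
#' @return A list with `times` (if available), `dilation` (per frame) and
#'   `peak`.
#' @export
max_radial_dilation <- function(x, ...) UseMethod("max_radial_dilation")

#' @rdname max_radial_dilation
#' @export
max_radial_dilation.mito_trajectory <- function(x, r_0a = x$config$r_0a, ...) {
  if (x$mode == "fixed")
    warning("fixed-axon trajectory: the membrane does not deform")
  list(times = x$series$time, dilation = x$series$max_radial_dilation,
       peak = max(x$series$max_radial_dilation))
}

#' @rdname max_radial_dilation
#' @export
max_radial_dilation.list <- function(x, r_0a, ...) {
  dil <- vapply(x, function(nodes) {
    max((sqrt(nodes[, 2]^2 + nodes[, 3]^2) - r_0a) / r_0a)
  }, numeric(1))
  list(times = NULL, dilation = dil, peak = max(dil))
}

#' Smoothed post-jam order summary of a run
#'
#' The minimum nematic order during the collision period (with `S_x` smoothed
#' by a centred moving average over `window` frames before taking the argmin,
#' to avoid single-frame noise) and the shape factor at that time, plus the
#' relief time and peak dilation.  The argmin window starts when injection
#' completes and ends when the population has drained below half its maximum,
#' so the near-empty tail of a run (a handful of arbitrarily oriented
#' stragglers) cannot masquerade as the jam minimum.
#'
#' @param traj a `mito_trajectory`.
#' @param window centred moving-average window (frames; odd).
#' @return A list: `tau` (s), `min_Sx`, `t_min_Sx` (s), `SF_at_min_Sx`,
#'   `peak_dilation`.
#' @export
jam_summary <- function(traj, window = 5) {
  s <- traj$series
  sel <- which(s$time >= traj$t_inject_end & !is.na(s$nematic_Sx) &
                 s$n_beads >= max(s$n_beads) / 2)
  min_sx <- t_min <- sf_at <- NA_real_
  if (length(sel) > 0) {
    sx <- s$nematic_Sx[sel]
    if (length(sx) >= window) {
      sm <- stats::filter(sx, rep(1 / window, window), sides = 2)
      sm[is.na(sm)] <- sx[is.na(sm)]
    } else sm <- sx
    im <- which.min(sm)
    min_sx <- sm[im]
    t_min <- s$time[sel[im]]
    sf_at <- s$shape_factor[sel[im]]
  }
  tau <- tryCatch(relief_time(traj), error = function(e) NA_real_)
  list(tau = as.numeric(tau), min_Sx = as.numeric(min_sx), t_min_Sx = t_min,
       SF_at_min_Sx = sf_at,
       peak_dilation = max(traj$series$max_radial_dilation))
}

#' Fit a four-parameter sigmoid
#'
#' Least-squares fit of `y = floor + (ceiling - floor) / (1 + exp(-slope *
#' (x - midpoint)))`, the dose-response form that describes relief times as a
#' function of log lifecycle rates.  The fitted curve is monotone by
#' construction.  Degenerate data (flat response) or non-convergence are
#' flagged, never silent.
#'
#' @param x predictor (typically log10 rate).
#' @param y response (typically relief time, s).
#' @return A `sigmoid_fit`: list with `parameters` (floor, ceiling, midpoint,
#'   slope), `residual_norm`, `converged`, `degenerate` and the underlying
#'   model.
#' @export
#' @examples
#' x <- seq(-2, 2, length.out = 9)
#' y <- 5 + 20 / (1 + exp(-2 * (x - 0.5)))
#' fit_sigmoid(x, y)$parameters
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 points spanning both plateaus")
  spread <- diff(range(y))
  if (spread <= 1e-12 * max(abs(y), 1)) {
    return(structure(list(
      parameters = c(floor = mean(y), ceiling = mean(y),
                     midpoint = median(x), slope = 0),
      residual_norm = sqrt(sum((y - mean(y))^2)),
      converged = TRUE, degenerate = TRUE, model = NULL,
      diagnostics = "constant response: ceiling ~ floor"), class = "sigmoid_fit"))
  }
  sgn <- if (is.na(cor(x, y)) || cor(x, y) >= 0) 1 else -1
  start <- list(fl = min(y), ce = max(y), mid = median(x),
                sl = sgn * 4 / diff(range(x)))
  df <- data.frame(x = x, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ fl + (ce - fl) / (1 + exp(-sl * (x - mid))), data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(
      parameters = c(floor = NA_real_, ceiling = NA_real_,
                     midpoint = NA_real_, slope = NA_real_),
      residual_norm = NA_real_, converged = FALSE, degenerate = FALSE,
      model = NULL, diagnostics = as.character(fit)), class = "sigmoid_fit"))
  }
  cf <- coef(fit)
  degenerate <- abs(cf[["ce"]] - cf[["fl"]]) <= 1e-3 * max(abs(y), 1e-12)
  structure(list(
    parameters = c(floor = cf[["fl"]], ceiling = cf[["ce"]],
                   midpoint = cf[["mid"]], slope = cf[["sl"]]),
    residual_norm = sqrt(sum(residuals(fit)^2)),
    converged = TRUE, degenerate = degenerate, model = fit,
    diagnostics = NULL), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>\n")
  print(round(x$parameters, 6))
  cat(sprintf("  residual norm %.4g; converged: %s; degenerate: %s\n",
              x$residual_norm, x$converged, x$degenerate))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata, ...) {
  p <- object$parameters
  xx <- if (is.data.frame(newdata)) newdata$x else newdata
  p[["floor"]] + (p[["ceiling"]] - p[["floor"]]) /
    (1 + exp(-p[["slope"]] * (xx - p[["midpoint"]])))
}

#' Fission-fusion phase diagram of relief times
#'
#' Runs one simulation per (k_fission, k_fusion) grid cell per seed and
#' tabulates the mean relief time.  Cells whose runs fail or never relieve
#' are flagged (`NA`) but the matrix is still returned.
#'
#' @param k_fission_values,k_fusion_values rate grids (1/s).
#' @param config base [sim_config()]; its rates and seed are overridden per
#'   cell.
#' @param seeds integer seeds averaged per cell.
#' @param csv optional path; when given, the matrix is also written as CSV.
#' @return A matrix (rows = fission rates, columns = fusion rates) of mean
#'   relief times (s), with attribute `"flagged"` marking failed cells.
#' @export
phase_diagram <- function(k_fission_values, k_fusion_values, config,
                          seeds = 1L, csv = NULL) {
  out <- matrix(NA_real_, length(k_fission_values), length(k_fusion_values),
                dimnames = list(paste0("fission_", k_fission_values),
                                paste0("fusion_", k_fusion_values)))
  flagged <- out
  for (i in seq_along(k_fission_values)) {
    for (j in seq_along(k_fusion_values)) {
      taus <- vapply(seeds, function(s) {
        cfg <- config
        cfg$k_fission <- k_fission_values[i]
        cfg$k_fusion <- k_fusion_values[j]
        cfg$seed <- as.integer(s)
        tr <- try(run_simulation(cfg, record_frames = FALSE), silent = TRUE)
        if (inherits(tr, "try-error")) return(NA_real_)
        as.numeric(relief_time(tr))
      }, numeric(1))
      out[i, j] <- mean(taus)
      flagged[i, j] <- any(is.na(taus))
    }
  }
  attr(out, "flagged") <- flagged
  if (!is.null(csv))
    write.table(cbind(k_fission = k_fission_values, as.data.frame(out)),
                csv, sep = ",", row.names = FALSE, quote = FALSE)
  out
}
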