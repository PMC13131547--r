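test_that("ensemble axial speed averages |v_x| over beads", {
  fr <- list(velocities = cbind(c(0.5e-6, -0.5e-6, 0.5e-6), 0, 0))
  expect_equal(ensemble_speed_x(fr), 0.5e-6)   # absolute value removes sign
  fr$velocities <- cbind(c(0, 0), 1e-6, -1e-6) # jammed: no axial motion
  expect_equal(ensemble_speed_x(fr), 0)
  expect_warning(v <- ensemble_speed_x(list(velocities = matrix(0, 0, 3))),
                 "no beads")
  expect_true(is.na(v))
})

test_that("relief time is the post-minimum recovery to 95% of v_0", {
  v0 <- 0.5e-6
  mk <- function(t, v) data.frame(time = t, mean_abs_vx = v * v0)
  # never drops below threshold: no jam, relief 0
  expect_equal(relief_time(mk(0:20, rep(1, 21)), v_0 = v0), 0)
  # constructed crossing: v0 until 5, 0.2 v0 until 12, v0 after -> tau = 12
  tt <- seq(0, 20, by = 0.5)
  vv <- ifelse(tt < 5, 1, ifelse(tt < 12, 0.2, 1))
  expect_equal(as.numeric(relief_time(mk(tt, vv), v_0 = v0)), 12)
  # search window excludes the injection transient
  vv2 <- ifelse(tt < 2, 0.1, ifelse(tt < 5, 1, ifelse(tt < 12, 0.2, 1)))
  expect_equal(as.numeric(relief_time(mk(tt, vv2), v_0 = v0, after = 3)), 12)
  # never recovered: flagged, not silent
  vv3 <- ifelse(tt < 5, 1, 0.2)
  tau <- relief_time(mk(tt, vv3), v_0 = v0)
  expect_true(is.na(tau))
  expect_equal(attr(tau, "status"), "unrelieved")
  # empty window errors
  expect_error(relief_time(mk(tt, vv), v_0 = v0, after = 100), "window")

  # uniform downward scaling of the recovery tail never shortens the relief
  base <- vv
  taus <- sapply(c(1, 0.99, 0.97), function(s) {
    v <- base; v[tt >= 12] <- v[tt >= 12] * s
    as.numeric(relief_time(mk(tt, v), v_0 = v0))
  })
  expect_true(all(diff(taus) >= 0))
})

test_that("nematic order hits its aligned, perpendicular and isotropic limits", {
  expect_equal(nematic_order_x(straight_chain(5)), 1)                  # along x
  expect_equal(nematic_order_x(straight_chain(5, axis = c(0, 1, 0))), -0.5)
  # isotropic bonds: 0 within 3 standard errors (1e5 bonds)
  set.seed(13)
  nb <- 1e5
  u <- matrix(rnorm(3 * (nb + 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- apply(u * 250e-9, 2, cumsum)   # a random walk: bonds are the u's
  st <- mito_state(pos, rep(1L, nb + 1), 1L)
  sx <- nematic_order_x(st)
  p2 <- (3 * u[, 1]^2 - 1) / 2
  expect_lt(abs(sx), 3 * sd(p2) / sqrt(nb))
  # bounds hold
  expect_lte(sx, 1); expect_gte(sx, -0.5)
  # single-bead populations are undefined under the bond definition
  expect_warning(v <- nematic_order_x(straight_chain(1)), "single beads")
  expect_true(is.na(v))
  # ... unless the polarity axis is substituted
  expect_equal(nematic_order_x(straight_chain(1), singles = "polarity"), 1)
})

test_that("shape factor matches the straight-chain closed form", {
  rm_ <- 125e-9
  # the worked value: an unperturbed 5-chain gives exactly 0.4
  expect_equal(shape_factor(straight_chain(5), rm_), 0.4)
  # single bead coincides with its centre of mass
  expect_equal(shape_factor(straight_chain(1), rm_), 0)
  # closed form (N^2 - 1) / (12 N) for N = 1..10, to 1e-12
  for (n in 1:10)
    expect_equal(shape_factor(straight_chain(n), rm_), (n^2 - 1) / (12 * n),
                 tolerance = 1e-12)
  # rotation and translation invariance (depends only on distances to the COM)
  set.seed(14)
  st <- straight_chain(7)
  st$pos <- st$pos + matrix(rnorm(21, sd = 2e-8), 7, 3)
  base <- shape_factor(st, rm_)
  for (i in 1:3) {
    R <- random_rotation()
    moved <- st
    moved$pos <- st$pos %*% t(R) + matrix(rnorm(3, sd = 1e-6), 7, 3, byrow = TRUE)
    expect_equal(shape_factor(moved, rm_), base, tolerance = 1e-12)
  }
  # averaged over chains
  st2 <- mito_state(rbind(straight_chain(5)$pos,
                          straight_chain(1, origin = c(3e-6, 0, 0))$pos),
                    rep(1:2, c(5, 1)), c(rep(1L, 5), 1L))
  expect_equal(shape_factor(st2, rm_), mean(c(0.4, 0)))
})

test_that("max radial dilation reports per-frame and peak deformation", {
  r0 <- 500e-9
  cyl <- small_mesh()$nodes
  one <- cyl
  one[1, 2:3] <- one[1, 2:3] / sqrt(sum(one[1, 2:3]^2)) * 650e-9
  res <- max_radial_dilation(list(cyl, one, cyl), r_0a = r0)
  expect_equal(res$dilation, c(0, 0.30, 0), tolerance = 1e-9)
  expect_equal(res$peak, 0.30, tolerance = 1e-9)
  expect_true(all(res$peak >= res$dilation))
})

test_that("sigmoid fits recover known parameters and flag degeneracy", {
  set.seed(15)
  x <- seq(-2, 2, length.out = 11)
  truth <- c(floor = 5, ceiling = 30, midpoint = 0.4, slope = 2.5)
  y <- truth["floor"] + (truth["ceiling"] - truth["floor"]) /
    (1 + exp(-truth["slope"] * (x - truth["midpoint"])))
  yn <- y * (1 + rnorm(length(y), sd = 0.01))
  fit <- fit_sigmoid(x, yn)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  for (p in names(truth))
    expect_lt(abs(fit$parameters[[p]] - truth[[p]]) / abs(truth[[p]]), 0.05)
  # the fitted curve is monotone in x
  grid <- predict(fit, seq(-3, 3, length.out = 200))
  expect_true(all(diff(grid) > 0))
  # constant response: ceiling ~ floor, flagged degenerate
  flat <- fit_sigmoid(x, rep(7, 11))
  expect_true(flat$degenerate)
  expect_equal(unname(flat$parameters["floor"]),
               unname(flat$parameters["ceiling"]))
  expect_error(fit_sigmoid(1:3, 1:3), "at least 5")
})

test_that("a zero-rate phase-diagram cell reproduces the static run exactly", {
  cfg <- sim_config(phi_fraction = 0.3, t_star = 12, seed = 21,
                    snapshot_stride = 100)
  pd <- phase_diagram(0, 0, cfg, seeds = 21)
  tr <- run_simulation(cfg, record_frames = FALSE)
  expect_equal(pd[1, 1], as.numeric(relief_time(tr)))
  csv <- tempfile(fileext = ".csv")
  pd2 <- phase_diagram(0, 0, cfg, seeds = 21, csv = csv)
  expect_true(file.exists(csv))
})
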