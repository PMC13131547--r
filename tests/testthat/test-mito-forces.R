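cfg <- sim_config()
rm_ <- cfg$r_m

bend_energy <- function(X, k_b) {
  # sum over interior triples of k_b * theta^2 / (8 r_m)
  E <- 0
  for (i in 2:(nrow(X) - 1)) {
    a <- X[i, ] - X[i - 1, ]
    b <- X[i + 1, ] - X[i, ]
    th <- acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
    E <- E + k_b * th^2 / (8 * rm_)
  }
  E
}

test_that("bending forces are the negative gradient of the quadratic bending energy", {
  # straight chain sits at the energy minimum: zero force
  st <- straight_chain(3)
  expect_equal(mito_bending_forces(st, cfg), matrix(0, 3, 3))
  # chains shorter than 3 beads have no bending triple
  expect_equal(mito_bending_forces(straight_chain(2), cfg), matrix(0, 2, 3))

  # right-angle bend: forces match central finite differences of U_b
  P <- rbind(c(0, 0, 0), c(2 * rm_, 0, 0), c(2 * rm_, 2 * rm_, 0))
  st <- mito_state(P, rep(1L, 3), 1L)
  Fb <- mito_bending_forces(st, cfg)
  Fd <- -num_grad(function(X) bend_energy(X, cfg$k_b_mito), P, eps = 1e-10)
  expect_lt(rel_err(Fb, Fd), 1e-5)
  # the central bead balances its neighbours exactly
  expect_equal(Fb[2, ], -(Fb[1, ] + Fb[3, ]))

  # randomized bent configurations, including longer chains
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    P <- matrix(0, n, 3)
    for (i in 2:n)
      P[i, ] <- P[i - 1, ] + 2 * rm_ * c(1, 0, 0) + rnorm(3, sd = 5e-8)
    st <- mito_state(P, rep(1L, n), 1L)
    Fb <- mito_bending_forces(st, cfg)
    Fd <- -num_grad(function(X) bend_energy(X, cfg$k_b_mito), P, eps = 1e-10)
    expect_lt(rel_err(Fb, Fd), 1e-5)
    expect_equal(colSums(Fb), c(0, 0, 0))   # internal momentum conservation
  }
})

test_that("spring forces are Hookean about one bead diameter", {
  # rest separation 2 r_m: no force
  expect_equal(mito_spring_forces(straight_chain(2), cfg), matrix(0, 2, 3))

  # 300 nm separation, k = 100 N/m: attractive 5e-6 N on each bead
  st <- mito_state(rbind(c(0, 0, 0), c(300e-9, 0, 0)), c(1L, 1L), 1L)
  Fs <- mito_spring_forces(st, cfg)
  expect_equal(Fs[1, 1], 5e-6)
  expect_equal(Fs[2, 1], -5e-6)
  expect_equal(Fs[1, ], -Fs[2, ])

  # energy-gradient check and momentum conservation on a random chain
  set.seed(8)
  P <- matrix(cumsum(c(0, runif(4, 2e-7, 3e-7))), 5, 3)
  P[, 2] <- rnorm(5, sd = 3e-8); P[, 3] <- rnorm(5, sd = 3e-8)
  st <- mito_state(P, rep(1L, 5), 1L)
  Us <- function(X) {
    d <- sqrt(rowSums((X[-1, ] - X[-5, ])^2))
    sum(0.5 * cfg$k_s_mito * (d - 2 * rm_)^2)
  }
  expect_lt(rel_err(mito_spring_forces(st, cfg), -num_grad(Us, P, eps = 1e-10)),
            1e-5)
  expect_equal(colSums(mito_spring_forces(st, cfg)), c(0, 0, 0))

  st$pos[2, ] <- st$pos[1, ]
  expect_error(mito_spring_forces(st, cfg), "degenerate")
})

test_that("steric repulsion acts only on overlapping non-bonded pairs", {
  two <- function(sep) mito_state(rbind(c(0, 0, 0), c(sep, 0, 0)),
                                  c(1L, 2L), c(1L, -1L))
  # beyond 2 r_m: exactly zero (Heaviside cutoff)
  expect_equal(mito_steric_forces(two(260e-9), cfg), matrix(0, 2, 3))
  # 200 nm: overlap 50 nm, k_M = 40 N/m -> 2e-6 N, repulsive
  Fs <- mito_steric_forces(two(200e-9), cfg)
  expect_equal(Fs[1, 1], -2e-6)
  expect_equal(Fs[2, 1], 2e-6)
  # chain-adjacent beads at 200 nm: excluded (the bonded spring handles them)
  st <- mito_state(rbind(c(0, 0, 0), c(200e-9, 0, 0)), c(1L, 1L), 1L)
  expect_equal(mito_steric_forces(st, cfg), matrix(0, 2, 3))
  # but second neighbours within a chain do interact
  st3 <- mito_state(rbind(c(0, 0, 0), c(150e-9, 150e-9, 0), c(220e-9, 0, 0)),
                    rep(1L, 3), 1L)
  expect_gt(abs(mito_steric_forces(st3, cfg)[1, 1]), 0)

  # energy-gradient oracle over a random crowded population (regenerate until
  # no pair sits right at the cutoff, where the energy is not differentiable)
  set.seed(9)
  repeat {
    P <- cbind(runif(12, 0, 1e-6), runif(12, -2e-7, 2e-7), runif(12, -2e-7, 2e-7))
    if (min(abs(dist(P) - 2 * rm_)) > 1e-8) break
  }
  st <- mito_state(P, rep(1:4, each = 3), rep(c(1L, -1L, 1L, -1L), each = 3))
  bc <- mitojam:::bead_chain_index(st)
  Ust <- function(X) {
    E <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      if (bc$chain[i] == bc$chain[j] && abs(bc$ord[i] - bc$ord[j]) == 1) next
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (r < 2 * rm_) E <- E + 0.5 * cfg$k_m_steric * (2 * rm_ - r)^2
    }
    E
  }
  expect_lt(rel_err(mito_steric_forces(st, cfg), -num_grad(Ust, P, eps = 1e-11)),
            1e-5)
  expect_equal(colSums(mito_steric_forces(st, cfg)), c(0, 0, 0),
               tolerance = 1e-20)
})

test_that("cell-list neighbour search reproduces the all-pairs loop exactly", {
  set.seed(10)
  n <- 80
  P <- cbind(runif(n, 0, 3e-6), runif(n, -3.5e-7, 3.5e-7),
             runif(n, -3.5e-7, 3.5e-7))
  st <- mito_state(P, seq_len(n), rep(c(1L, -1L), n / 2))
  expect_identical(mito_steric_forces(st, cfg, "cell"),
                   mito_steric_forces(st, cfg, "brute"))
  mesh <- small_mesh()
  expect_identical(wca_forces(st, mesh, cfg, "cell"),
                   wca_forces(st, mesh, cfg, "brute"))
})

test_that("WCA bead-membrane contact is repulsive, truncated and reciprocal", {
  node <- matrix(c(0, 0, 0), 1, 3)
  at <- function(r) mito_state(matrix(c(r, 0, 0), 1, 3), 1L, 1L)
  cutoff <- 2^(1 / 6) * rm_

  # zero at the cutoff, and continuous from below
  expect_equal(wca_forces(at(cutoff), node, cfg)$bead_forces, matrix(0, 1, 3))
  expect_lt(abs(wca_forces(at(cutoff * (1 - 1e-9)), node, cfg)$bead_forces[1, 1]),
            1e-12)
  # separation r_m: magnitude 24 phi_0 / r_m = 9.6e-7 N, pushing the bead away
  fw <- wca_forces(at(rm_), node, cfg)
  expect_equal(fw$bead_forces[1, 1], 24 * cfg$phi_0 / rm_)
  expect_equal(fw$bead_forces[1, 1], 9.6e-7)
  # node receives the exact negative (reciprocity with the membrane)
  expect_equal(fw$bead_forces, -fw$node_forces)

  # matches -grad of the truncated-shifted LJ energy at random separations
  Uw <- function(r) {
    if (r >= cutoff) return(0)
    4 * cfg$phi_0 * ((rm_ / r)^12 - (rm_ / r)^6) + cfg$phi_0
  }
  set.seed(11)
  for (r in runif(5, 0.6 * rm_, 1.1 * rm_)) {
    eps <- 1e-13
    expect_lt(abs(wca_forces(at(r), node, cfg)$bead_forces[1, 1] -
                  (-(Uw(r + eps) - Uw(r - eps)) / (2 * eps))) /
              abs(wca_forces(at(r), node, cfg)$bead_forces[1, 1]), 1e-4)
  }

  # pairs below the floor distance are clamped with a warning
  expect_warning(wca_forces(at(0.05 * rm_), node, cfg), "clamped")
})

test_that("pair forces are isotropic under rigid rotations", {
  set.seed(12)
  P <- rbind(c(0, 0, 0), c(2.3e-7, 4e-8, 0), c(4.1e-7, 1.5e-7, 8e-8))
  st <- mito_state(P, rep(1L, 3), 1L)
  for (rep in 1:3) {
    R <- random_rotation()
    str <- rotate_state(st, R)
    expect_equal(mito_bending_forces(str, cfg),
                 mito_bending_forces(st, cfg) %*% t(R), tolerance = 1e-10)
    expect_equal(mito_spring_forces(str, cfg),
                 mito_spring_forces(st, cfg) %*% t(R), tolerance = 1e-10)
  }
})

test_that("the overdamped step combines drift and propulsion", {
  cfg1 <- sim_config(gamma_m = 1)
  # isolated anterograde bead, zero force: +0.5 nm in 1 ms
  st <- mito_state(matrix(0, 1, 3), 1L, 1L)
  out <- step_mitochondria(st, matrix(0, 1, 3), cfg1, dt = 1e-3)
  expect_equal(out$pos[1, ], c(0.5e-9, 0, 0))
  # retrograde: mirrored
  str <- mito_state(matrix(0, 1, 3), 1L, -1L)
  expect_equal(step_mitochondria(str, matrix(0, 1, 3), cfg1, dt = 1e-3)$pos[1, ],
               c(-0.5e-9, 0, 0))
  # zero propulsion limit: displacement F dt / gamma exactly
  cfg0 <- sim_config(v_a = 1e-30, v_r = 1e-30)
  Fm <- matrix(c(1e-7, -2e-7, 3e-7), 1, 3)
  out <- step_mitochondria(st, Fm, cfg0, dt = 1e-3)
  expect_equal(out$pos[1, ], as.numeric(Fm) * 1e-3, tolerance = 1e-12)
  # the instantaneous rates are recorded for the observables
  expect_equal(attr(out, "velocities"), Fm / cfg0$gamma_m + c(1e-30, 0, 0))
})
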