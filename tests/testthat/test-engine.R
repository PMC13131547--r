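test_that("injection places chains at the ends with shared disc coordinates", {
  cfg <- sim_config(n_chain = 5)
  set.seed(1)
  st <- inject_mitochondria(mitojam:::empty_mito_state(), cfg, "anterograde")
  # rear bead at x = 0, spacing one bead diameter
  expect_equal(st$pos[, 1], c(0, 250, 500, 750, 1000) * 1e-9)
  expect_equal(length(unique(st$pos[, 2])), 1L)   # shared (y, z)
  expect_equal(length(unique(st$pos[, 3])), 1L)
  expect_true(all(st$polarity == 1L))

  st2 <- inject_mitochondria(st, cfg, "retrograde")
  newb <- st2$pos[6:10, ]
  expect_equal(newb[, 1], 3.8e-6 - c(0, 250, 500, 750, 1000) * 1e-9)
  expect_true(all(st2$polarity[6:10] == -1L))
  expect_identical(st2$particle_id, 1:10)         # fresh unique ids
  expect_identical(unique(st2$chain_id), c(1L, 2L))

  # all injected beads stay clear of the membrane
  set.seed(2)
  for (i in 1:20) {
    s <- inject_mitochondria(mitojam:::empty_mito_state(), cfg, "anterograde")
    expect_true(all(s$pos[, 2]^2 + s$pos[, 3]^2 <= (cfg$r_0a - cfg$r_m)^2))
  }
})

test_that("escape removal deletes whole out-of-domain chains and keeps stragglers", {
  cfg <- sim_config(removal = "chain")
  gone <- straight_chain(3, origin = c(cfg$L + 1e-9, 0, 0), chain_id = 1L)
  straddle <- straight_chain(3, origin = c(cfg$L - 1e-9, 0, 0), chain_id = 2L)
  inside <- straight_chain(3, origin = c(1e-6, 0, 0), chain_id = 3L)
  st <- mito_state(rbind(gone$pos, straddle$pos, inside$pos),
                   rep(1:3, each = 3), rep(1L, 9))
  out <- remove_escaped(st, cfg)
  expect_identical(sort(unique(out$chain_id)), c(2L, 3L))
  expect_identical(attr(out, "removed_beads"), 3L)
  # conservation bookkeeping: original = retained + removed
  expect_identical(n_beads(st), n_beads(out) + attr(out, "removed_beads"))
  # fully below x = 0 is removed too
  back <- straight_chain(2, origin = c(-1e-6, 0, 0), axis = c(-1, 0, 0))
  expect_identical(n_beads(remove_escaped(back, cfg)), 0L)

  # per-bead removal shortens a straddling chain bead by bead
  cfgB <- sim_config(removal = "bead")
  outB <- remove_escaped(straddle, cfgB)
  expect_identical(n_beads(outB), 1L)      # only the bead still inside stays
  expect_identical(attr(outB, "removed_beads"), 2L)

  # exit removal is directional: beads leave only through their target end
  cfgE <- sim_config(removal = "exit")
  past_L <- straight_chain(2, origin = c(cfgE$L + 1e-9, 0, 0), polarity = 1L)
  expect_identical(n_beads(remove_escaped(past_L, cfgE)), 0L)
  # a retrograde chain shoved past x = L is retained (it has not arrived)
  past_L$polarity <- rep(-1L, 2)
  expect_identical(n_beads(remove_escaped(past_L, cfgE)), 2L)
  # and a retrograde bead below x = 0 has arrived at the soma side
  below <- straight_chain(1, origin = c(-1e-9, 0, 0), polarity = -1L)
  expect_identical(n_beads(remove_escaped(below, cfgE)), 0L)
})

test_that("a membrane-only deformable run stays at numerical equilibrium", {
  cfg <- sim_config(phi_fraction = 1e-6, mode = "deformable", t_star = 0.3,
                    snapshot_stride = 30, seed = 1)
  expect_equal(density_to_bead_count(cfg$phi_fraction, cfg), 0L)
  tr <- run_simulation(cfg, record_frames = FALSE)
  expect_lt(max(tr$series$max_node_speed), 1e-6 * cfg$v_0)
  expect_equal(max(tr$series$max_radial_dilation), 0)
})

test_that("an unobstructed chain transits the axon at the propulsion speed", {
  cfg <- sim_config(phi_fraction = 1e-6, n_initial_pairs = 0, t_star = 8,
                    snapshot_stride = 20, seed = 3)
  st <- straight_chain(5, origin = c(0, 1e-7, 0))
  tr <- run_simulation(cfg, record_frames = FALSE, initial_state = st)
  # the ensemble speed equals v_a exactly while the chain is in flight
  mid <- tr$series[tr$series$time > 1 & tr$series$time < 7, ]
  expect_equal(max(abs(mid$mean_abs_vx - cfg$v_a)), 0, tolerance = 1e-3 * cfg$v_a)
  # the rear bead reaches x = L at t = L / v_a = 7.6 s within 1%
  t_exit <- tr$series$time[which(tr$series$n_beads == 0)[1]]
  expect_lt(abs(t_exit - 7.6), 0.076)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(phi_fraction = 0.3, t_star = 1.5, seed = 11,
                    snapshot_stride = 50, k_fission = 5, k_fusion = 5)
  a <- run_simulation(cfg, record_frames = TRUE)
  b <- run_simulation(cfg, record_frames = TRUE)
  expect_identical(a$series, b$series)
  expect_identical(lapply(a$frames, `[[`, "state"),
                   lapply(b$frames, `[[`, "state"))
  # and a different seed differs
  cfg2 <- sim_config(phi_fraction = 0.3, t_star = 1.5, seed = 12,
                     snapshot_stride = 50, k_fission = 5, k_fusion = 5)
  expect_false(identical(run_simulation(cfg2, record_frames = FALSE)$series,
                         a$series))
})

test_that("dimensionless and SI integrations agree after rescaling", {
  cfg <- sim_config(phi_fraction = 0.3, t_star = 1, seed = 5,
                    snapshot_stride = 100)
  nd <- run_simulation(cfg, record_frames = TRUE)
  si <- run_simulation(cfg, record_frames = TRUE, units = "si")
  expect_equal(si$series$mean_abs_vx, nd$series$mean_abs_vx,
               tolerance = 1e-10)
  last <- length(nd$frames)
  expect_equal(si$frames[[last]]$state$pos, nd$frames[[last]]$state$pos,
               tolerance = 1e-10)
})

test_that("bead bookkeeping balances and the population stays confined", {
  cfg <- sim_config(phi_fraction = 0.3, t_star = 6, seed = 2,
                    snapshot_stride = 100)
  tr <- run_simulation(cfg, record_frames = TRUE)
  expect_equal(tr$injected, n_beads(tr$final_state) + tr$removed)
  # no membrane penetration: bead centres stay within r_0a (+ 0.05 r_m)
  for (fr in tr$frames) {
    if (n_beads(fr$state) == 0) next
    r <- sqrt(fr$state$pos[, 2]^2 + fr$state$pos[, 3]^2)
    expect_lt(max(r), cfg$r_0a + 0.05 * cfg$r_m)
  }
  # injection completed and was recorded
  expect_false(is.na(tr$t_inject_end))
  expect_gte(max(tr$series$n_beads), density_to_bead_count(0.3, cfg))
})
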