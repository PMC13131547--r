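cfg <- sim_config(k_fission = 1, k_fusion = 1)
rm_ <- cfg$r_m

test_that("fission splits chains at a uniformly random internal bond", {
  st <- straight_chain(5)

  # zero rate: untouched
  cfg0 <- sim_config(k_fission = 0)
  expect_identical(fission_step(st, cfg0, dt = 10), st)

  # saturated probability: every chain of length >= 2 splits exactly once
  set.seed(1)
  cfgS <- sim_config(k_fission = 10)
  out <- fission_step(st, cfgS, dt = 1)
  expect_equal(nrow(chain_table(out)), 2L)
  expect_identical(sort(out$particle_id), sort(st$particle_id))
  expect_true(all(out$polarity == 1L))           # fragments inherit polarity
  # single beads never split
  single <- straight_chain(1)
  expect_equal(nrow(chain_table(fission_step(single, cfgS, dt = 1))), 1L)

  # Monte-Carlo rate recovery: 1e4 steps at k dt = 0.1
  set.seed(2)
  cfgR <- sim_config(k_fission = 100)
  dt <- 1e-3                                     # p = 0.1
  n_trials <- 1e4
  splits <- 0L
  sizes <- integer(0)
  for (i in seq_len(n_trials)) {
    out <- fission_step(st, cfgR, dt)
    ct <- chain_table(out)
    if (nrow(ct) == 2) {
      splits <- splits + 1L
      sizes <- c(sizes, ct$length[1])
    }
  }
  p_hat <- splits / n_trials
  se <- sqrt(0.1 * 0.9 / n_trials)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  # the severed bond is uniform over the 4 internal bonds
  expect_gt(stats::chisq.test(table(factor(sizes, levels = 1:4)))$p.value, 1e-3)
})

test_that("fusion requires proximity, alignment and the rate draw", {
  cfgF <- sim_config(k_fusion = 10)   # p saturates at dt = 1

  two_chains <- function(gap, angle = 0, pol2 = 1L) {
    a <- straight_chain(5, chain_id = 1L)
    dir <- c(cos(angle), sin(angle), 0)
    b_origin <- c(4 * 2 * rm_ + gap, 0, 0)
    b <- straight_chain(5, origin = b_origin, axis = dir, polarity = pol2,
                        chain_id = 2L)
    mito_state(rbind(a$pos, b$pos), c(a$chain_id, b$chain_id),
               c(a$polarity, b$polarity))
  }

  # termini 300 nm apart exceed r_fusion = 275 nm: never fuse
  set.seed(3)
  out <- fusion_step(two_chains(300e-9), cfgF, dt = 1)
  expect_equal(nrow(chain_table(out)), 2L)

  # orientation difference 45 degrees > 30-degree cutoff: never fuse
  set.seed(4)
  out <- fusion_step(two_chains(260e-9, angle = 45 * pi / 180), cfgF, dt = 1)
  expect_equal(nrow(chain_table(out)), 2L)

  # collinear same-polarity chains within range: deterministic fusion
  set.seed(5)
  out <- fusion_step(two_chains(260e-9), cfgF, dt = 1)
  ct <- chain_table(out)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$length, 10L)
  expect_equal(ct$polarity, 1L)
  expect_identical(sort(out$particle_id), 1:10)

  # zero rate: connectivity is time-invariant
  cfg0 <- sim_config(k_fusion = 0)
  st <- two_chains(260e-9)
  expect_identical(fusion_step(st, cfg0, dt = 1), st)

  # Monte-Carlo recovery of the fusion probability min(k dt, 1)
  set.seed(6)
  st <- two_chains(260e-9)
  cfgR <- sim_config(k_fusion = 0.3)
  hits <- 0L
  n_trials <- 1e4
  for (i in seq_len(n_trials))
    if (nrow(chain_table(fusion_step(st, cfgR, dt = 1))) == 1) hits <- hits + 1L
  se <- sqrt(0.3 * 0.7 / n_trials)
  expect_lt(abs(hits / n_trials - 0.3), 3 * se)
})

test_that("mixed-polarity fusion picks the fused direction at random", {
  # an anterograde chain and a retrograde-labelled chain whose end-to-end
  # vectors both point +x (orientation difference 0 <= cutoff), termini in
  # range: only the polarity rule distinguishes the outcomes
  a <- straight_chain(2, chain_id = 1L, polarity = 1L)
  b <- straight_chain(2, origin = c(2 * 2 * 125e-9 + 10e-9, 0, 0),
                      chain_id = 2L, polarity = -1L)
  st <- mito_state(rbind(a$pos, b$pos), c(1L, 1L, 2L, 2L), c(1L, 1L, -1L, -1L))
  cfgF <- sim_config(k_fusion = 10)
  set.seed(7)
  pols <- replicate(200, {
    out <- fusion_step(st, cfgF, dt = 1)
    if (nrow(chain_table(out)) == 1) chain_table(out)$polarity else NA_integer_
  })
  pols <- pols[!is.na(pols)]
  expect_gt(length(pols), 100)
  expect_gt(sum(pols == 1), 0)
  expect_gt(sum(pols == -1), 0)
  expect_lt(abs(mean(pols == 1) - 0.5), 3 * sqrt(0.25 / length(pols)))
})

test_that("bead count and particle ids are invariant under lifecycle sequences", {
  set.seed(8)
  st <- do.call(function(...) {
    chains <- list(...)
    mito_state(do.call(rbind, lapply(chains, `[[`, "pos")),
               unlist(lapply(chains, `[[`, "chain_id")),
               unlist(lapply(chains, `[[`, "polarity")))
  }, lapply(1:6, function(i)
    straight_chain(sample(1:5, 1), origin = c(runif(1, 0, 3e-6), 0, 0),
                   chain_id = i, polarity = sample(c(-1L, 1L), 1))))
  ids <- sort(st$particle_id)
  n0 <- n_beads(st)
  cfgB <- sim_config(k_fission = 50, k_fusion = 50)
  cur <- st
  for (step in 1:50) {
    cur <- fission_step(cur, cfgB, dt = 0.02)
    cur <- fusion_step(cur, cfgB, dt = 0.02)
    expect_identical(n_beads(cur), n0)
    expect_identical(sort(cur$particle_id), ids)
    ct <- chain_table(cur)
    expect_true(all(ct$length >= 1))                  # no empty chains
    expect_identical(sum(ct$length), n0)              # chain ids partition beads
  }
})

test_that("mean chain length tracks fission halving", {
  expect_equal(mean_chain_length(straight_chain(5)), 5)
  # one fission of a 5-chain into 2 + 3
  st <- straight_chain(5)
  st$chain_id <- c(1L, 1L, 2L, 2L, 2L)
  expect_equal(mean_chain_length(st), 2.5)
  expect_error(mean_chain_length(mitojam:::empty_mito_state()), "empty")

  # saturated fission reaches all-singletons within ceil(log2 5) + 1 steps
  set.seed(9)
  cfgS <- sim_config(k_fission = 10)
  cur <- straight_chain(5)
  lens <- numeric(0)
  for (i in seq_len(ceiling(log2(5)) + 1)) {
    cur <- fission_step(cur, cfgS, dt = 1)
    lens <- c(lens, mean_chain_length(cur))
  }
  expect_equal(tail(lens, 1), 1)
  expect_true(all(diff(lens) <= 0))   # fission-only: non-increasing
})
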