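tiny_config <- function(...) {
  walk_config(nx = 3, ny = 3, nz = 3, n_ligate = 1, n_channels = 1,
              arrangement = "clustered", n_steps = 10, n_reps = 1, ...)
}

test_that("configuration defaults match the reference geometry", {
  cfg <- walk_config()
  expect_equal(cfg$step_nm, 33)
  expect_equal(c(cfg$nx, cfg$ny, cfg$nz), c(32, 32, 16))
  expect_equal(cfg$n_ligate, 2127)
  expect_equal(cfg$n_channels, 44)
  expect_equal(cfg$n_steps, 500)
  expect_equal(cfg$n_reps, 1000)
  # 6 uM in the 1,056 x 1,056 x 528 nm cuboid gives exactly 2,127 molecules
  expect_equal(ligates_from_concentration(6), 2127)
  expect_equal(walk_config(from_concentration_uM = 6)$n_ligate, 2127)
})

test_that("channel layouts satisfy their packing constraints", {
  cl <- idnodes:::channel_layout(walk_config(arrangement = "clustered"))
  expect_equal(nrow(cl), 44)
  expect_lte(diff(range(cl[, 1])) + 1, 7)
  expect_lte(diff(range(cl[, 2])) + 1, 7)
  dst <- idnodes:::channel_layout(walk_config(arrangement = "distributed"))
  expect_equal(nrow(dst), 44)
  expect_gte(min(dist(dst)), 4)
  expect_error(walk_config(n_channels = 33 * 33, nx = 32, ny = 32),
               "more channels than face sites")
})

test_that("initial states are deterministic and channel-site free", {
  cfg <- walk_config(seed = 12, n_steps = 5)
  s1 <- init_state(cfg)
  s2 <- init_state(cfg)
  expect_identical(s1$ligate, s2$ligate)
  chan_keys <- s1$channels[, 1] + 1000 * s1$channels[, 2]
  lig0 <- s1$ligate[s1$ligate[, 3] == 0, , drop = FALSE]
  expect_false(any((lig0[, 1] + 1000 * lig0[, 2]) %in% chan_keys))
})

test_that("particle number is conserved and occupancy is bounded", {
  cfg <- walk_config(n_ligate = 200, n_channels = 10, p_bind = 0.5,
                     p_unbind = 0.05, n_steps = 200, seed = 3)
  tr <- run_walk(cfg)
  expect_length(tr$bound_trace, 200)
  expect_true(all(tr$bound_trace >= 0 & tr$bound_trace <= 10))
  expect_equal(nrow(tr$state$ligate), 200)
  expect_true(all(tr$state$ligate[, 1] >= 0 & tr$state$ligate[, 1] < 32))
  expect_true(all(tr$state$ligate[, 3] >= 0 & tr$state$ligate[, 3] < 16))
  # determinism under seed
  tr2 <- run_walk(cfg)
  expect_identical(tr$bound_trace, tr2$bound_trace)
  expect_identical(tr$state$ligate, tr2$state$ligate)
})

test_that("binding edge cases behave as specified", {
  cfg0 <- walk_config(p_bind = 0, p_unbind = 0.1, n_steps = 100,
                      n_ligate = 100, seed = 2)
  expect_true(all(run_walk(cfg0)$bound_trace == 0))

  cfg1 <- walk_config(nx = 8, ny = 8, nz = 4, n_ligate = 60, n_channels = 4,
                      p_bind = 1, p_unbind = 0, n_steps = 400, seed = 4)
  bt <- run_walk(cfg1)$bound_trace
  expect_true(all(diff(bt) >= 0))          # absorbing binding
  expect_equal(max(bt), 4)                 # saturates at n_channels
})

test_that("free diffusion has linear mean-square displacement", {
  # walkers start at the lattice center so the reflecting boundary is not
  # reached over the horizon; E[r^2] = t lattice steps for the 6-neighbour
  # walk
  cfg <- walk_config(nx = 41, ny = 41, nz = 41, n_ligate = 800,
                     n_channels = 0, p_bind = 0, p_unbind = 0,
                     n_steps = 1, seed = 6)
  center <- matrix(rep(20L, 3 * 800), ncol = 3, byrow = TRUE)
  msd_at <- function(t) {
    st0 <- structure(list(ligate = center, bound = rep(-1L, 800),
                          channels = matrix(integer(0), 0, 2), step = 0L,
                          config = cfg),
                     class = "walk_state")
    st <- with_seed_local(9, step_walk(st0, t))
    mean(rowSums((st$ligate - center)^2))
  }
  for (t in c(60, 120)) {
    expect_lt(abs(msd_at(t) / t - 1), 0.05)
  }
})

test_that("stationary bound fraction matches the exact Markov chain", {
  p_bind <- 0.6; p_unbind <- 0.08; attraction <- 2
  cfg <- walk_config(nx = 3, ny = 3, nz = 3, n_ligate = 1, n_channels = 1,
                     p_bind = p_bind, p_unbind = p_unbind,
                     attraction = attraction, n_steps = 40000, seed = 21)
  ch <- idnodes:::channel_layout(cfg)
  oracle <- oracle_walk_chain(3, 3, 3, as.integer(ch[1, ]),
                              p_bind, p_unbind, attraction)
  tr <- run_walk(cfg)
  burn <- 2000
  sim_bound <- mean(tr$bound_trace[-seq_len(burn)])
  # autocorrelated binary trace: use a generous effective-sample-size bound
  n_eff <- (cfg$n_steps - burn) / 50
  se <- sqrt(oracle$p_bound * (1 - oracle$p_bound) / n_eff)
  expect_lt(abs(sim_bound - oracle$p_bound), 4 * se)

  kd <- estimate_kd(tr, window = 0.5)
  v_L <- walk_volume_L(cfg)
  pb <- oracle$p_bound
  kd_exact <- ((1 - pb) / (6.02214076e23 * v_L) * 1e9) * (1 - pb) / pb
  expect_lt(abs(kd$kd_nM - kd_exact) / kd_exact, 0.10)
})

test_that("Kd equals the free-ligand concentration at half occupancy", {
  cfg <- walk_config(n_channels = 44, n_ligate = 2127, n_steps = 10, seed = 1)
  fake <- structure(list(bound_trace = rep(22, 10), config = cfg),
                    class = "walk_trace")
  kd <- estimate_kd(fake, window = 0.4)
  expect_equal(kd$kd_nM, kd$free_conc_nM)

  none <- structure(list(bound_trace = rep(0, 10), config = cfg),
                    class = "walk_trace")
  kd0 <- estimate_kd(none)
  expect_true(kd0$infinite)
  expect_equal(kd0$kd_nM, Inf)
})

test_that("calibration flags infinite rows and tracks the target", {
  cfg <- walk_config(nx = 8, ny = 8, nz = 4, n_ligate = 80, n_channels = 4,
                     n_steps = 150, seed = 5)
  tab <- calibrate_probabilities(200, p_bind_grid = c(0, 0.5),
                                 p_unbind_grid = c(0.01), cfg, n_reps = 2,
                                 seed = 5)
  expect_true(tab$infinite[tab$p_bind == 0])
  expect_false(tab$infinite[tab$p_bind == 0.5])
  expect_equal(tab$abs_error_nM, sort(tab$abs_error_nM))
  expect_error(calibrate_probabilities(100, numeric(0), numeric(0), cfg),
               "empty probability grid")
})

test_that("Kd is non-decreasing in the unbind probability", {
  cfg <- walk_config(p_bind = 0.5, attraction = 4, seed = 31)
  kds <- vapply(c(2e-4, 1e-3, 4e-3, 1.6e-2, 6e-2), function(pu) {
    c2 <- cfg; c2$p_unbind <- pu
    mean(run_walk_reps(c2, n_reps = 3, seed = 17)$kd_nM)
  }, numeric(1))
  expect_true(all(diff(kds) > 0))
})

test_that("an A/A arrangement comparison is exactly null", {
  cfg <- walk_config(nx = 8, ny = 8, nz = 4, n_ligate = 80, n_channels = 4,
                     p_bind = 0.5, p_unbind = 0.01, n_steps = 200,
                     arrangement = "clustered", seed = 13)
  a <- run_walk_reps(cfg, n_reps = 4, seed = 13)
  b <- run_walk_reps(cfg, n_reps = 4, seed = 13)
  expect_identical(a$kd_nM, b$kd_nM)
})

test_that("the strict exclusion variant runs and stays conservative", {
  cfg <- walk_config(nx = 8, ny = 8, nz = 4, n_ligate = 60, n_channels = 9,
                     p_bind = 0.8, p_unbind = 0.01, n_steps = 200,
                     exclusion = TRUE, seed = 19)
  tr <- run_walk(cfg)
  expect_true(all(tr$bound_trace <= 9))
  expect_identical(run_walk(cfg)$bound_trace, tr$bound_trace)
})
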