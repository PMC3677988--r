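test_that("trajectories respect the dynamical invariants", {
  sim <- mini_sim()
  expect_in_unit_interval(sim$p)
  expect_gte(min(sim$r), 0)
  expect_equal(nrow(sim$u), length(sim$times))
  ## rate recomputed from u matches the stored field
  B <- vapply(seq_along(sim$times), function(i)
    divisive_inhibition(sim$u[i, ], sim$grid, sim$params), numeric(1))
  expect_true(all(B >= 1))
  expect_equal(sim$r[10, ], firing_rate(sim$u[10, ], B[10]))
})

test_that("replay reproduces a run exactly and rejects short logs", {
  sim <- mini_sim()
  again <- replay(sim)
  expect_identical(again$u, sim$u)
  expect_identical(again$p, sim$p)
  ## seeded re-simulation is also identical
  s2 <- simulate_cann(std_params, cann_stimulus(0, sigma = 0.3),
                      duration = 300, transient = 100, seed = 7,
                      grid = ring_grid(16))
  s3 <- simulate_cann(std_params, cann_stimulus(0, sigma = 0.3),
                      duration = 300, transient = 100, seed = 7,
                      grid = ring_grid(16))
  expect_identical(s2$u, s3$u)
  short <- sim$flucts
  short$delta <- short$delta[1:3, , drop = FALSE]
  expect_error(replay(sim, flucts = short), "fluctuation log")
})

test_that("shifting stimuli by grid multiples rotates the trajectory", {
  g <- ring_grid(N = 16)
  m <- 3L
  stim0 <- cann_stimulus(c(-0.4, 0.4), A = 0.8, sigma = 0.3)
  set.seed(11)
  log <- draw_fluctuations(stim0, 12)
  base <- simulate_cann(std_params, stim0, duration = 600, transient = 300,
                        flucts = log, grid = g)
  shift_z <- function(z) ((z + m * g$dx + g$L / 2) %% g$L) - g$L / 2
  stim_s <- cann_stimulus(shift_z(c(-0.4, 0.4)), A = 0.8, sigma = 0.3)
  shifted <- simulate_cann(std_params, stim_s, duration = 600,
                           transient = 300, flucts = log, grid = g)
  rot <- function(M) M[, (seq_len(16) - 1L - m) %% 16 + 1L]
  expect_equal(shifted$u, rot(base$u), tolerance = 1e-10)
  expect_equal(shifted$p, rot(base$p), tolerance = 1e-10)
})

test_that("mirroring stimuli and swapping noise streams mirrors the run", {
  g <- ring_grid(N = 16)
  stim <- cann_stimulus(c(-0.4, 0.6), A = 0.8, sigma = 0.3)
  set.seed(12)
  log <- draw_fluctuations(stim, 12)
  base <- simulate_cann(std_params, stim, duration = 600, transient = 300,
                        flucts = log, grid = g)
  mlog <- log
  mlog$delta <- log$delta[, 2:1]
  mstim <- cann_stimulus(c(-0.6, 0.4), A = 0.8, sigma = 0.3)
  mir <- simulate_cann(std_params, mstim, duration = 600, transient = 300,
                       flucts = mlog, grid = g)
  ## x -> -x maps grid index i to the index of -x[i] (wrapping x = -pi)
  idx <- vapply(seq_len(16), function(i)
    which.min(ring_distance(g$x, -g$x[i])), integer(1))
  expect_equal(mir$u, base$u[, idx], tolerance = 1e-10)
})

test_that("halving the tolerances barely changes the trajectory", {
  stim <- cann_stimulus(c(-0.5, 0.5), A = 0.8, sigma = 0.3)
  set.seed(3)
  log <- draw_fluctuations(stim, 20)
  s1 <- simulate_cann(std_params, stim, duration = 1000, transient = 500,
                      flucts = log)
  s2 <- simulate_cann(std_params, stim, duration = 1000, transient = 500,
                      flucts = log, rtol = 5e-7, atol = 5e-7)
  expect_lt(max(abs(s1$u - s2$u)), 1e-4)
})

test_that("a no-input bump relaxes monotonically onto the attractor", {
  g <- ring_grid()
  a <- std_params$a
  init <- list(u = 4 * exp(-ring_distance(g$x, 0, g$L)^2 / (4 * a^2)),
               p = rep(1, g$N))
  sim <- simulate_cann(cann_params(beta = 0), cann_stimulus(0, A = 0, sigma = 0),
                       duration = 400, transient = 200, init = init)
  h <- sim$h
  expect_true(all(diff(h) > -1e-5))          # no oscillation on approach
  expect_equal(max(sim$u[nrow(sim$u), ]), bump_heights(0.5)$u0,
               tolerance = 0.005)
})

test_that("integration failures and bad cadence are reported", {
  expect_error(simulate_cann(std_params, cann_stimulus(0), duration = 100,
                             transient = 200), "duration")
  expect_error(simulate_cann(std_params, cann_stimulus(0, refresh = 50),
                             duration = 300, transient = 100,
                             sample_interval = 7), "sample_interval")
})

test_that("trajectory export writes a complete, replayable directory", {
  sim <- mini_sim()
  dir <- withr::local_tempdir()
  write_trajectory(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scalars.csv", "u.csv", "p.csv", "r.csv", "flucts.csv", "config.json")))))
  log <- read_fluctuation_log(file.path(dir, "flucts.csv"))
  again <- simulate_cann(sim$params, sim$stimulus, duration = sim$duration,
                         transient = sim$transient, flucts = log,
                         grid = sim$grid)
  expect_identical(again$u, sim$u)
})
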