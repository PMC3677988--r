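test_that("peak detection thresholds and orders samples correctly", {
  sim <- mini_sim()
  all_pk <- detect_peaks(sim, threshold = 0)
  expect_equal(nrow(all_pk), sum(sim$times > sim$transient))
  expect_true(all(all_pk$height >= 0))
  none <- detect_peaks(sim, threshold = max(sim$h) + 1)
  expect_equal(nrow(none), 0)
  ## raising the threshold never adds samples (monotonicity)
  n_by_thr <- vapply(c(0, 1, 2, 4, 8), function(th)
    nrow(detect_peaks(sim, th)), numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
  ## event mode returns a subset of sample mode: spike apexes only
  ev <- detect_peaks(sim, threshold = 0, mode = "event")
  expect_lt(nrow(ev), nrow(all_pk))
  expect_true(all(ev$time %in% all_pk$time))
})

test_that("histograms are grid-aligned, max-normalized and mirror-symmetric", {
  g <- ring_grid()
  one <- data.frame(time = 1:5, position = g$x[11], height = 7)
  h1 <- peak_histogram(one, g)
  expect_equal(sum(h1$count), 5)
  expect_equal(h1$weight[11], 1)
  expect_equal(sum(h1$weight > 0), 1)
  ## mass conservation and mirroring
  set.seed(2)
  pos <- sample(g$x, 500, replace = TRUE, prob = exp(-g$x^2))
  pk <- data.frame(time = seq_along(pos), position = pos, height = 7)
  hh <- peak_histogram(pk, g)
  expect_equal(sum(hh$count), 500)
  mirrored <- pk
  mirrored$position <- vapply(pos, function(z)
    g$x[which.min(ring_distance(g$x, -z))], numeric(1))
  hm <- peak_histogram(mirrored, g)
  idx <- vapply(seq_len(80), function(i)
    which.min(ring_distance(g$x, -g$x[i])), integer(1))
  expect_equal(hm$count[idx], hh$count)
})

test_that("two-mode structure finds side modes and honors tracking", {
  g <- ring_grid()
  mk <- function(centers, n = 400, spread = 0.12) {
    set.seed(5)
    pos <- g$x[pmin(pmax(round((unlist(lapply(centers, function(z)
      rnorm(n, z, spread))) + pi) / g$dx), 0), 79) + 1]
    peak_histogram(data.frame(time = 1, position = pos, height = 7), g)
  }
  two <- mk(c(-0.8, 0.8))
  res <- two_mode_structure(two)
  expect_true(res$bimodal)
  expect_equal(sort(res$modes), c(-0.8, 0.8), tolerance = 0.15)
  one <- mk(0)
  expect_false(two_mode_structure(one)$bimodal)
  ## tracking: far-out modes rejected against close expected positions
  expect_false(two_mode_structure(two, expected = c(-0.15, 0.15))$bimodal)
  expect_true(two_mode_structure(two, expected = c(-0.75, 0.75))$bimodal)
})

test_that("gaussian mixtures split exactly above twice the component width", {
  fx <- make_fixture("gauss-mix")
  res <- split_separation(fx$profiles, fx$dz)
  ## independent oracle: dense evaluation of the continuous mixture
  oracle_bimodal <- vapply(fx$dz, function(d) {
    z <- d * fx$a
    f <- function(x) exp(-(x - z)^2 / (2 * fx$a^2)) +
                     exp(-(x + z)^2 / (2 * fx$a^2))
    xs <- seq(-2 * z, 2 * z, length.out = 4001)
    y <- f(xs)
    modes <- which(diff(sign(diff(y))) == -2) + 1
    length(modes) >= 2 && (min(y[modes]) - f(0)) >= 0.02 * max(y)
  }, logical(1))
  expect_equal(res$bimodal, oracle_bimodal)
  expect_equal(res$split, fx$dz[which(oracle_bimodal)[1]])
  expect_gt(res$split, 1)      # strictly above one tuning width
  expect_true(res$monotone)
  ## single-component profiles never split
  g <- ring_grid()
  solo <- lapply(fx$dz, function(d)
    data.frame(x = g$x, r = exp(-g$x^2 / (2 * fx$a^2))))
  expect_true(is.na(split_separation(solo, fx$dz)$split))
})

test_that("cluster separation statistics match hand-built configurations", {
  g <- ring_grid()
  a <- std_params$a
  dz <- 1.2 * 2 * a
  pk <- data.frame(time = 1:40,
                   position = rep(c(-dz / 2, dz / 2), 20), height = 7)
  res <- mean_peak_separation(pk, midpoint = 0, a = a)
  expect_equal(res$separation, 1.2, tolerance = 1e-12)
  expect_equal(res$sd, c(0, 0))
  expect_false(res$low_confidence)
  ## k-means rule agrees on cleanly separated clusters
  set.seed(9)
  pos <- c(rnorm(200, -dz / 2, 0.1), rnorm(200, dz / 2, 0.1))
  pk2 <- data.frame(time = 1:400, position = pos, height = 7)
  r_mid <- mean_peak_separation(pk2, 0, a, rule = "midpoint")
  r_km <- mean_peak_separation(pk2, 0, a, rule = "kmeans")
  expect_equal(r_mid$separation, r_km$separation, tolerance = 1e-6)
  ## degenerate single-sided data flags low confidence
  lone <- data.frame(time = 1:5, position = rep(0.3, 5), height = 7)
  expect_true(mean_peak_separation(lone, 0, a)$low_confidence)
})

test_that("time-averaged profile reduces to the steady profile for a static run", {
  sim <- cached("static_run",
    simulate_cann(std_params, cann_stimulus(0, A = 2.0, sigma = 0),
                  duration = 1500, transient = 1000, seed = 4))
  pr <- time_averaged_profile(sim)
  expect_equal(pr$r, sim$r[nrow(sim$r), ], tolerance = 1e-4)
  expect_equal(pr$x, sim$grid$x)
})

test_that("bias-conditioned maps localize mass and reflect with the input", {
  ## zero fluctuations: every step sits in the central bias bin
  sim0 <- cached("static_run",
    simulate_cann(std_params, cann_stimulus(0, A = 2.0, sigma = 0),
                  duration = 1500, transient = 1000, seed = 4))
  sim0$flucts$delta <- cbind(sim0$flucts$delta, sim0$flucts$delta)  # fake 2nd comp
  bm0 <- bias_conditioned_map(sim0, threshold = 0)
  mid <- ceiling(length(bm0$bias_mid) / 2)
  expect_equal(sum(bm0$n), sum(bm0$n[mid, mid]))
  ## mirrored log point-reflects the map
  g16 <- ring_grid(16)
  stim <- cann_stimulus(c(-0.4, 0.4), A = 0.8, sigma = 0.3)
  set.seed(21)
  log <- draw_fluctuations(stim, 30)
  s1 <- simulate_cann(std_params, stim, duration = 1500, transient = 500,
                      flucts = log, grid = g16)
  mlog <- log; mlog$delta <- log$delta[, 2:1]
  s2 <- simulate_cann(std_params, stim, duration = 1500, transient = 500,
                      flucts = mlog, grid = g16)
  b1 <- bias_conditioned_map(s1, threshold = 0)
  b2 <- bias_conditioned_map(s2, threshold = 0)
  nb <- length(b1$bias_mid)
  flip <- nb:1
  expect_equal(b2$n, b1$n[flip, flip])
  expect_equal(b2$mean_pos, -b1$mean_pos[flip, flip], tolerance = 1e-8)
})
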