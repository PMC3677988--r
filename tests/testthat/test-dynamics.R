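test_that("divisive inhibition matches closed forms", {
  g <- ring_grid()
  pars <- cann_params()
  expect_equal(divisive_inhibition(rep(0, 80), g, pars), 1)
  ## constant field: B = 1 + k/(8 sqrt(2 pi) a) * c^2 * L
  cc <- 1.7
  expect_equal(divisive_inhibition(rep(cc, 80), g, pars),
               1 + pars$k / (8 * sqrt(2 * pi) * pars$a) * cc^2 * g$L)
  ## local mode with huge b approaches the global value
  u <- exp(-g$x^2)
  loc <- cann_params(inhibition = "local", b = 100 * pars$a)
  expect_equal(max(abs(divisive_inhibition(u, g, loc) -
                       divisive_inhibition(u, g, pars))), 0, tolerance = 1e-4)
  expect_true(all(divisive_inhibition(u, g, loc) >= 1))
})

test_that("firing rate squares, rectifies and divides", {
  expect_equal(firing_rate(-1, 5), 0)
  expect_equal(firing_rate(2, 2), 2)
  expect_equal(firing_rate(0, 1), 0)
  expect_error(firing_rate(1, 0.5), "inhibition")
  ## squaring narrows a Gaussian current by sqrt(2) in SD
  x <- seq(-2, 2, length.out = 201)
  u <- exp(-x^2 / (2 * 1.3^2))
  r <- firing_rate(u, 1)
  expect_equal(r, exp(-x^2 / (2 * (1.3 / sqrt(2))^2)))
})

test_that("recurrent derivatives vanish at rest and match steady-state algebra", {
  g <- ring_grid()
  pars <- cann_params()
  W <- excitatory_kernel(g, pars$a)
  d <- cann_rhs(rep(0, 80), rep(1, 80), rep(0, 80), pars, W, g)
  expect_equal(d$du, rep(0, 80))
  expect_equal(d$dp, rep(0, 80))
  ## with the rate clamped, dp = 0 at p* = 1/(1 + beta r)
  pars2 <- cann_params(beta = 0.25)
  B <- divisive_inhibition(rep(2, 80), g, pars2)  # u = 2 everywhere
  r <- firing_rate(rep(2, 80), B)
  p_star <- 1 / (1 + pars2$beta * r)
  d2 <- cann_rhs(rep(2, 80), p_star, rep(0, 80), pars2, W, g)
  expect_equal(d2$dp, rep(0, 80), tolerance = 1e-12)
  expect_error(cann_rhs(rep(0, 40), rep(1, 80), rep(0, 80), pars, W, g),
               "dimensions")
})

test_that("kernel evaluation equals the direct double-loop integral", {
  g <- ring_grid(N = 32)
  pars <- cann_params()
  W <- excitatory_kernel(g, pars$a)
  set.seed(8)
  u <- rnorm(32)
  p <- runif(32)
  B <- divisive_inhibition(u, g, pars)
  r <- firing_rate(u, B)
  drive <- numeric(32)
  for (i in 1:32)
    for (j in 1:32)
      drive[i] <- drive[i] + g$dx / (sqrt(2 * pi) * pars$a) *
        exp(-ring_distance(g$x[i], g$x[j])^2 / (2 * pars$a^2)) * p[j] * r[j]
  d <- cann_rhs(u, p, rep(0, 32), pars, W, g)
  expect_equal(d$du, -u + drive, tolerance = 1e-12)
})

test_that("feedforward derivatives vanish without input and obey p*", {
  g <- ring_grid()
  fp <- ff_params()
  K <- feedforward_kernel(g, fp)
  d <- ff_rhs(rep(0, 80), rep(1, 80), rep(0, 80), fp, K, g)
  expect_equal(d$du, rep(0, 80))
  expect_equal(d$dp, rep(0, 80))
  ## constant input clamp: p* = 1/(1 + beta I)
  I <- rep(0.6, 80)
  p_star <- rep(1 / (1 + fp$beta * 0.6), 80)
  d2 <- ff_rhs(rep(0, 80), p_star, I, fp, K, g)
  expect_equal(d2$dp, rep(0, 80), tolerance = 1e-12)
})

test_that("parameter validation enforces model constraints", {
  expect_error(cann_params(k = -0.1))
  expect_error(cann_params(inhibition = "local"), "'b'")
  expect_error(cann_params(inhibition = "local", b = 0.1), "'b'")
  expect_error(ff_params(JI = 1.2), "JI")
  expect_error(ff_params(b = 0.1), "'b'")
  expect_error(bump_heights(1.5), "bump")
  expect_equal(bump_heights(0.5)$u0, 2 * sqrt(2) * (1 + sqrt(0.5)) / 0.5)
})
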