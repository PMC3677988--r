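# Shared fixtures.  Expensive simulations are cached per test session so
# that several test files (in particular the acceptance checks) can share
# one run.  Cached trajectories are slimmed to their scalar readouts and
# time-averaged profile; peak statistics only need those.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

std_params <- cann_params()            # k = 0.5, beta = 0.24
TW <- 2 * std_params$a                 # tuning width, 96 deg in radians
GRID <- ring_grid()

## Drop the field matrices, keep scalar readouts + time-averaged profile.
slim <- function(sim) {
  profile <- time_averaged_profile(sim)
  sim$u <- sim$p <- sim$r <- NULL
  list(sim = sim, profile = profile)
}

## Long run with stimuli at given centers (radians) under the standard
## spiking parameters; cached and slimmed.
long_run <- function(centers, beta = 0.24, sigma = 0.3, A = 0.8,
                     duration = 20000, seed = NULL) {
  key <- sprintf("run_%s_%g_%g_%g_%g", paste(signif(centers, 6), collapse = "_"),
                 beta, sigma, A, duration)
  cached(key, {
    if (is.null(seed)) seed <- 7000 + round(1e4 * sum(abs(centers))) %% 100000
    slim(simulate_cann(cann_params(k = 0.5, beta = beta),
                       cann_stimulus(centers, A = A, sigma = sigma),
                       duration = duration, transient = 1000, seed = seed))
  })
}

## Symmetric two-stimulus run, separation in tuning widths.
two_stim_run <- function(dz_tw, ...) {
  d <- dz_tw * TW
  long_run(c(-d / 2, d / 2), ...)
}

## Regime exemplar runs (short; single or two stimuli).
regime_of <- function(A, beta, centers = 0, sigma = 0, duration = 3000,
                      seed = 50) {
  key <- sprintf("reg_%g_%g_%g_%g", A, beta, sigma, sum(centers))
  sim <- cached(key,
    simulate_cann(cann_params(k = 0.5, beta = beta),
                  cann_stimulus(centers, A = A, sigma = sigma),
                  duration = duration, transient = 1000, seed = seed))
  classify_regime(sim)
}

## Small fast network for unit tests (16 units, short runs).
mini_sim <- function() cached("mini", make_fixture("mini")$sim)

expect_in_unit_interval <- function(x, tol = 1e-6) {
  expect_gte(min(x), -tol)
  expect_lte(max(x), 1 + tol)
}
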