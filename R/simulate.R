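#' Simulate the ring network through time
#'
#' Integrates the rescaled field equations with the piecewise-constant
#' stochastic input.  Integration restarts at every fluctuation refresh
#' so the input discontinuity never crosses an adaptive step; within a
#' segment the dynamics are smooth and an adaptive explicit Runge-Kutta
#' pair (Dormand-Prince 5(4) by default) integrates them at local
#' tolerance `rtol`/`atol`.  Initial conditions are `u = 0`, `p = 1`.
#'
#' The sampled trajectory records the current `u`, the neurotransmitter
#' fraction `p` and the rate `r` every `sample_interval` time units
#' (default 1; the recovery time constant of 50 then gives at least 50
#' samples per population-spike cycle).  The first `transient` time units
#' (default 20 recovery times) are kept in the trajectory but excluded
#' from all downstream statistics.
#'
#' @param params A [cann_params()] or [ff_params()] object.
#' @param stimulus A [cann_stimulus()].
#' @param duration Total integration time in synaptic time units.
#' @param sample_interval State-recording cadence (must divide evenly
#'   into the refresh interval).
#' @param transient Initial span excluded from statistics.
#' @param seed Optional integer seed for the fluctuation draws.
#' @param flucts Optional [draw_fluctuations()] log to replay; must cover
#'   the duration.  When given, no random numbers are drawn.
#' @param grid A [ring_grid()] (default 80 units on 360 degrees).
#' @param rtol,atol Local error tolerances of the adaptive stepper.
#' @param method A `deSolve` Runge-Kutta method name (default
#'   `"rk45dp7"`; `"rk78f"` gives a higher-order pair).
#' @param init Optional initial state, a list with fields `u` and `p`
#'   (default: `u = 0`, `p = 1`).  Used e.g. to relax a prepared bump
#'   under zero input (`A = 0`).
#' @return An object of class `cann_sim`: a list with `times`, matrices
#'   `u`, `p`, `r` (samples in rows, units in columns), `h` (peak rate
#'   per sample), `pos` (peak position per sample), the realized
#'   `flucts`, and the configuration (`grid`, `params`, `stimulus`,
#'   `duration`, `transient`, `sample_interval`, `seed`, tolerances).
#' @examples
#' sim <- simulate_cann(cann_params(), cann_stimulus(0, A = 0.8, sigma = 0),
#'                      duration = 200, transient = 100, seed = 1)
#' range(sim$p)    # neurotransmitter fraction stays in [0, 1]
#' @export
simulate_cann <- function(params, stimulus, duration = 2000,
                          sample_interval = 1, transient = 1000,
                          seed = NULL, flucts = NULL, grid = ring_grid(),
                          rtol = 1e-6, atol = 1e-6, method = "rk45dp7",
                          init = NULL) {
  stopifnot(inherits(params, c("cann_params", "ff_params")),
            inherits(stimulus, "cann_stimulus"),
            inherits(grid, "ring_grid"))
  if (duration <= transient || transient < 0)
    stop("'duration' must exceed 'transient' (>= 0)", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  refresh <- stimulus$refresh
  if (abs(refresh / sample_interval - round(refresh / sample_interval)) > 1e-9)
    stop("'sample_interval' must divide the refresh interval", call. = FALSE)
  n_steps <- as.integer(ceiling(duration / refresh))

  if (is.null(flucts)) {
    if (!is.null(seed)) set.seed(seed)
    flucts <- draw_fluctuations(stimulus, n_steps)
  } else {
    stopifnot(inherits(flucts, "fluctuation_log"))
    if (nrow(flucts$delta) < n_steps)
      stop(sprintf(
        "fluctuation log covers %g tau_s but the run needs %g",
        nrow(flucts$delta) * refresh, duration), call. = FALSE)
  }

  feedforward <- inherits(params, "ff_params")
  a_I <- stimulus$a_I %||% params$a_I
  kernel <- if (feedforward) feedforward_kernel(grid, params)
            else excitatory_kernel(grid, params$a)
  kpref <- if (feedforward) NULL else params$k / (8 * sqrt(2 * pi) * params$a)
  local_kb <- NULL
  if (!feedforward && params$inhibition == "local") {
    local_kb <- ring_gauss_matrix(grid, params$b)
    if (params$b_prefactor == "gaussian")
      local_kb <- local_kb / (sqrt(2 * pi) * params$b)
  }
  N <- grid$N
  dx <- grid$dx
  tau_d <- params$tau_d
  beta <- params$beta

  ## deSolve right-hand side over the stacked state y = c(u, p);
  ## the input field within a segment is fixed in `env$I`.
  env <- new.env(parent = emptyenv())
  deriv <- if (feedforward) {
    function(t, y, parms) {
      u <- y[1:N]; p <- y[(N + 1):(2 * N)]
      I <- env$I
      list(c(-u + as.numeric(kernel %*% (p * I)),
             (-p + 1 - beta * p * I) / tau_d))
    }
  } else if (is.null(local_kb)) {
    function(t, y, parms) {
      u <- y[1:N]; p <- y[(N + 1):(2 * N)]
      B <- 1 + kpref * sum(u^2) * dx
      r <- pmax(u, 0)^2 / B
      list(c(-u + env$I + as.numeric(kernel %*% (p * r)),
             (-p + 1 - beta * p * r) / tau_d))
    }
  } else {
    function(t, y, parms) {
      u <- y[1:N]; p <- y[(N + 1):(2 * N)]
      B <- as.numeric(1 + kpref * dx * (local_kb %*% u^2))
      r <- pmax(u, 0)^2 / B
      list(c(-u + env$I + as.numeric(kernel %*% (p * r)),
             (-p + 1 - beta * p * r) / tau_d))
    }
  }

  rk <- deSolve::rkMethod(method)
  seg_times <- seq(0, refresh, by = sample_interval)
  n_keep <- as.integer(floor(duration / sample_interval))
  times <- seq_len(n_keep) * sample_interval
  u_out <- matrix(NA_real_, n_keep, N)
  p_out <- matrix(NA_real_, n_keep, N)
  y <- if (is.null(init)) c(rep(0, N), rep(1, N)) else {
    stopifnot(length(init$u) == N, length(init$p) == N)
    c(init$u, init$p)
  }
  row <- 0L
  E <- vapply(stimulus$centers,
              function(z) exp(-ring_distance(grid$x, z, grid$L)^2 / (2 * a_I^2)),
              numeric(N))

  for (m in seq_len(n_steps)) {
    t0 <- (m - 1) * refresh
    env$I <- normalize_input(as.numeric(E %*% (1 + flucts$delta[m, ])),
                             stimulus$A)
    t_end <- min(refresh, duration - t0)
    loc <- seg_times[seg_times <= t_end + 1e-9]
    if (length(loc) < 2L) break
    sol <- deSolve::ode(y, loc, deriv, parms = NULL, method = rk,
                        rtol = rtol, atol = atol)
    if (nrow(sol) < length(loc) || anyNA(sol[nrow(sol), ]))
      stop(sprintf("integration failed near t = %.6g tau_s",
                   t0 + sol[nrow(sol), 1L]), call. = FALSE)
    y <- as.numeric(sol[nrow(sol), -1L])
    keep <- seq_len(nrow(sol) - 1L)
    u_out[row + keep, ] <- sol[-1L, 2:(N + 1), drop = FALSE]
    p_out[row + keep, ] <- sol[-1L, (N + 2):(2 * N + 1), drop = FALSE]
    row <- row + length(keep)
  }
  if (row < n_keep) {  # duration not a refresh multiple: drop unfilled rows
    times <- times[seq_len(row)]
    u_out <- u_out[seq_len(row), , drop = FALSE]
    p_out <- p_out[seq_len(row), , drop = FALSE]
  }

  ## rate readout at sample times
  if (feedforward) {
    r_out <- pmax(u_out, 0)
  } else if (is.null(local_kb)) {
    B <- 1 + kpref * rowSums(u_out^2) * dx
    r_out <- pmax(u_out, 0)^2 / B
  } else {
    B <- 1 + kpref * dx * (u_out^2 %*% t(local_kb))
    r_out <- pmax(u_out, 0)^2 / B
  }
  imax <- max.col(r_out, ties.method = "first")
  h <- r_out[cbind(seq_len(nrow(r_out)), imax)]

  structure(list(times = times, u = u_out, p = p_out, r = r_out,
                 h = h, pos = grid$x[imax],
                 flucts = flucts, grid = grid, params = params,
                 stimulus = stimulus, duration = duration,
                 transient = transient, sample_interval = sample_interval,
                 seed = seed, rtol = rtol, atol = atol, method = method),
            class = "cann_sim")
}

#' Replay a recorded run
#'
#' Re-integrates a simulation from its stored configuration and
#' fluctuation log.  With identical integrator settings the result is
#' identical to the original run.
#'
#' @param sim A `cann_sim` object.
#' @param ... Overrides passed on to [simulate_cann()] (e.g. tighter
#'   tolerances).
#' @return A `cann_sim`.
#' @export
replay <- function(sim, ...) {
  stopifnot(inherits(sim, "cann_sim"))
  args <- list(params = sim$params, stimulus = sim$stimulus,
               duration = sim$duration, sample_interval = sim$sample_interval,
               transient = sim$transient, flucts = sim$flucts,
               grid = sim$grid, rtol = sim$rtol, atol = sim$atol,
               method = sim$method)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulate_cann, args)
}

## logical index of post-transient samples
post_transient <- function(sim) sim$times > sim$transient

#' @export
print.cann_sim <- function(x, ...) {
  cat(sprintf("CANN simulation: %g tau_s (%d samples of %d units), %s model\n",
              x$duration, length(x$times), x$grid$N,
              if (inherits(x$params, "ff_params")) "feedforward" else "recurrent"))
  post <- post_transient(x)
  cat(sprintf("  peak rate after transient (%g tau_s): max %.3g, mean %.3g\n",
              x$transient, max(x$h[post]), mean(x$h[post])))
  invisible(x)
}

#' @export
summary.cann_sim <- function(object, ...) {
  post <- post_transient(object)
  h <- object$h[post]
  out <- list(duration = object$duration, transient = object$transient,
              n_samples = sum(post),
              h_max = max(h), h_min = min(h), h_mean = mean(h),
              modulation = (max(h) - min(h)) / (max(h) + min(h)),
              p_range = range(object$p))
  class(out) <- "summary.cann_sim"
  out
}

#' @export
print.summary.cann_sim <- function(x, ...) {
  cat(sprintf(
    "Post-transient peak rate: max %.3g, min %.3g, mean %.3g (modulation index %.3f)\n",
    x$h_max, x$h_min, x$h_mean, x$modulation))
  cat(sprintf("Neurotransmitter fraction range: [%.4g, %.4g]\n",
              x$p_range[1], x$p_range[2]))
  invisible(x)
}

#' Raster plot of a simulated trajectory
#'
#' Displays the firing-rate field as an image over time and preferred
#' stimulus, the standard raster view of population-spike dynamics.
#'
#' @param x A `cann_sim`.
#' @param what Which field to display (`"r"`, `"u"` or `"p"`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.cann_sim <- function(x, what = c("r", "u", "p"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  graphics::image(x$times, x$grid$x, z, xlab = "time (tau_s)",
                  ylab = "preferred stimulus (rad)",
                  main = sprintf("%s(x, t)", what),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Export a trajectory as plain-text tables
#'
#' Writes `times.csv`, `u.csv`, `p.csv`, `r.csv`, the fluctuation log and
#' a JSON snapshot of the configuration into a directory.  Together with
#' [replay()], the directory contents reproduce the run exactly.
#'
#' @param sim A `cann_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(sim, dir) {
  stopifnot(inherits(sim, "cann_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time = sim$times, h = sim$h, pos = sim$pos),
                   file.path(dir, "scalars.csv"), row.names = FALSE)
  for (f in c("u", "p", "r"))
    utils::write.csv(sim[[f]], file.path(dir, paste0(f, ".csv")),
                     row.names = FALSE)
  write_fluctuation_log(sim$flucts, file.path(dir, "flucts.csv"))
  cfg <- list(model = unclass(sim$params),
              model_class = class(sim$params),
              stimulus = unclass(sim$stimulus),
              grid = list(N = sim$grid$N, L = sim$grid$L),
              duration = sim$duration, transient = sim$transient,
              sample_interval = sim$sample_interval, seed = sim$seed,
              rtol = sim$rtol, atol = sim$atol, method = sim$method)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
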