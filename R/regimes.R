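#' Classify the dynamical regime of a run
#'
#' Labels a trajectory as `silent`, `static_bump`, `population_spikes`,
#' `moving_bump` or `slosher` from post-transient diagnostics of the
#' peak rate `h(t)` and peak position `z(t)`:
#'
#' * `silent` -- the network is never driven beyond a small fraction of
#'   the self-sustained bump rate: `max h < silent_frac * r0(k)` (the
#'   analytic attractor height from [bump_heights()] sets the
#'   population-spike scale).
#' * `moving_bump` -- the unwrapped peak position drifts by more than
#'   `drift_frac * L` over the window.
#' * `population_spikes` -- the height-modulation index
#'   `(max h - min h)/(max h + min h)` reaches `spike_mod`.
#' * `slosher` -- height modulation below `spike_mod` but the detrended
#'   position oscillates with amplitude at least `slosh_amp * a`.
#' * `static_bump` -- otherwise.
#'
#' The thresholds operationalize raster-plot phenomenology; the defaults
#' separate the reference single-stimulus and slosher exemplars with
#' wide margins (measured indices: spikes 0.45, slosher 0.03, static
#' 0.00) and are exposed for sensitivity analysis.
#'
#' @param sim A `cann_sim` (recurrent model).
#' @param silent_frac,spike_mod,slosh_amp,drift_frac Decision-tree
#'   thresholds, see above.
#' @return An object of class `regime_label`: a list with `label` and a
#'   `diagnostics` vector (`h_max`, `h_mean`, `modulation`, `drift_rad`,
#'   `osc_rad`).
#' @export
classify_regime <- function(sim, silent_frac = 0.1, spike_mod = 0.25,
                            slosh_amp = 0.25, drift_frac = 0.5) {
  stopifnot(inherits(sim, "cann_sim"))
  if (sim$duration < 2 * sim$transient)
    stop("trajectory too short to classify: need duration >= 2 * transient",
         call. = FALSE)
  post <- post_transient(sim)
  h <- sim$h[post]
  pos <- sim$pos[post]
  L <- sim$grid$L

  ## nearest-image unwrapping of the peak-position track
  dpos <- ring_offset(diff(pos), 0, L)
  up <- cumsum(c(pos[1L], dpos))
  drift <- abs(up[length(up)] - up[1L])
  trend <- seq(up[1L], up[length(up)], length.out = length(up))
  osc <- diff(stats::quantile(up - trend, c(0.025, 0.975))) / 2
  mod <- (max(h) - min(h)) / (max(h) + min(h))

  k <- sim$params$k
  scale_r <- if (!inherits(sim$params, "ff_params") && k > 0 && k <= 1)
    bump_heights(k)$r0 else max(sim$h)
  label <- if (max(h) < silent_frac * scale_r) "silent"
    else if (drift > drift_frac * L) "moving_bump"
    else if (mod >= spike_mod) "population_spikes"
    else if (osc >= slosh_amp * sim$params$a) "slosher"
    else "static_bump"

  structure(list(label = label,
                 diagnostics = c(h_max = max(h), h_mean = mean(h),
                                 modulation = mod, drift_rad = drift,
                                 osc_rad = unname(osc))),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "Regime: %s (h_max %.3g, modulation %.2f, drift %.2f rad, oscillation %.3f rad)\n",
    x$label, d["h_max"], d["modulation"], d["drift_rad"], d["osc_rad"]))
  invisible(x)
}

#' Regime phase diagram over input strength and depression
#'
#' Classifies one run per cell of an (input strength, depression
#' strength) grid at fixed inhibition, the sweep that maps where
#' population spikes live.  Each cell uses an independent seed derived
#' from the base seed.
#'
#' @param A_values Input strengths to sweep.
#' @param beta_values Depression strengths to sweep.
#' @param k Inhibition strength (fixed across the sweep).
#' @param centers Stimulus component positions (default single stimulus
#'   at 0).
#' @param sigma Relative input fluctuation (default 0: the
#'   single-stimulus input is invariant under max-normalized
#'   fluctuations anyway).
#' @param duration,transient Span per run; the classification window is
#'   `duration - transient` (at least 40 recovery times by default).
#' @param seed Base seed.
#' @param grid A [ring_grid()].
#' @param ... Threshold overrides for [classify_regime()].
#' @return An object of class `phase_diagram`: a data frame with one
#'   row per cell (`A`, `beta`, `label`, diagnostics).
#' @export
phase_diagram <- function(A_values, beta_values, k = 0.5, centers = 0,
                          sigma = 0, duration = 3000, transient = 1000,
                          seed = 1, grid = ring_grid(), ...) {
  stopifnot(length(A_values) >= 1L, length(beta_values) >= 1L)
  cells <- expand.grid(A = A_values, beta = beta_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pars <- cann_params(k = k, beta = cells$beta[i])
    stim <- cann_stimulus(centers = centers, A = cells$A[i], sigma = sigma)
    sim <- simulate_cann(pars, stim, duration = duration,
                         transient = transient, seed = seed + i, grid = grid)
    lab <- classify_regime(sim, ...)
    cbind(cells[i, , drop = FALSE], label = lab$label,
          as.data.frame(as.list(lab$diagnostics)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' @export
plot.phase_diagram <- function(x, ...) {
  labs <- sort(unique(x$label))
  graphics::plot(x$A, x$beta, pch = 22, cex = 2.2,
                 bg = grDevices::hcl.colors(length(labs), "Set 2")[match(x$label, labs)],
                 xlab = "input strength A", ylab = "depression strength beta", ...)
  graphics::legend("topright", legend = labs, pt.bg = grDevices::hcl.colors(length(labs), "Set 2"),
                   pch = 22, bty = "n")
  invisible(x)
}
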