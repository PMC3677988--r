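#' Thresholded population-spike peak samples
#'
#' Extracts the peak of the firing-rate profile at each post-transient
#' sample time: its grid position (the argmax, ties broken towards the
#' smallest index) and its height.  Only samples whose height reaches
#' `threshold` are returned.  In `"sample"` mode (the default) every
#' qualifying sample time contributes one row, giving time-occupancy
#' statistics; in `"event"` mode only local maxima of the peak-height
#' time series contribute, one row per population-spike apex.
#'
#' @param sim A [simulate_cann()] trajectory.
#' @param threshold Minimum peak rate (default 6.2, the reference value
#'   for the recurrent model at the standard spiking parameters; the
#'   feedforward variant uses 0.45).
#' @param mode `"sample"` or `"event"`.
#' @return A data frame with columns `time`, `position`, `height` (may
#'   have zero rows).
#' @export
detect_peaks <- function(sim, threshold = 6.2, mode = c("sample", "event")) {
  stopifnot(inherits(sim, "cann_sim"))
  mode <- match.arg(mode)
  post <- post_transient(sim)
  t <- sim$times[post]; h <- sim$h[post]; pos <- sim$pos[post]
  if (mode == "event" && length(h) > 2L) {
    n <- length(h)
    apex <- c(FALSE, h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n],
              FALSE)
    t <- t[apex]; h <- h[apex]; pos <- pos[apex]
  }
  sel <- h >= threshold
  data.frame(time = t[sel], position = pos[sel], height = h[sel])
}

#' Histogram of peak positions on the grid
#'
#' Bins peak positions into one bin per grid cell (the bin centered on
#' each unit's preferred stimulus) and max-normalizes the counts, the
#' standard presentation of population-spike position distributions.
#'
#' @param peaks A data frame from [detect_peaks()].
#' @param grid The [ring_grid()] the simulation used.
#' @return An object of class `peak_histogram`: a data frame with
#'   columns `x` (bin center), `count` and `weight` (count / max count),
#'   with the total sample count in attribute `n`.
#' @export
peak_histogram <- function(peaks, grid) {
  stopifnot(inherits(grid, "ring_grid"))
  idx <- round((peaks$position + grid$L / 2) / grid$dx) %% grid$N + 1L
  counts <- tabulate(idx, nbins = grid$N)
  out <- data.frame(x = grid$x, count = counts,
                    weight = if (any(counts > 0)) counts / max(counts)
                             else counts)
  attr(out, "n") <- nrow(peaks)
  class(out) <- c("peak_histogram", "data.frame")
  out
}

#' @export
plot.peak_histogram <- function(x, ...) {
  graphics::plot(x$x, x$weight, type = "h", xlab = "position (rad)",
                 ylab = "normalized weight", ...)
  invisible(x)
}

## Circular moving average of half-width `smooth` bins (0 = identity).
ring_smooth <- function(y, smooth = 1) {
  if (smooth <= 0) return(y)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[((i - smooth - 1):(i + smooth - 1)) %% n + 1L])
  }, numeric(1))
}

## Two-sided mode test about a midpoint.  `y` is a nonnegative profile
## over positions `off` (signed offsets from the midpoint).  The highest
## bin on each side is a mode candidate; the profile is bimodal when
## both modes exceed the valley between them (the minimum over bins
## strictly inside the candidates' offset interval, which contains the
## midpoint) by `prominence * max(y)`.  Returns the verdict and the two
## mode offsets.
side_mode_test <- function(y, off, prominence) {
  iL <- which(off < 0)
  iR <- which(off > 0)
  fail <- list(bimodal = FALSE, modes = c(NA_real_, NA_real_))
  if (!length(iL) || !length(iR) || max(y) <= 0) return(fail)
  mL <- iL[which.max(y[iL])]
  mR <- iR[which.max(y[iR])]
  inner <- which(off > off[mL] & off < off[mR])
  if (!length(inner)) return(fail)
  dip <- min(y[inner])
  if (min(y[mL], y[mR]) - dip < prominence * max(y)) return(fail)
  list(bimodal = TRUE, modes = c(off[mL], off[mR]))
}

#' Two-mode structure of a peak-position distribution
#'
#' Tests whether a peak-position histogram resolves two stimulus
#' components: after light circular smoothing, the two highest modes
#' must lie on opposite sides of the stimulus midpoint and each must
#' rise above the valley between them by at least `prominence` times the
#' histogram maximum.
#'
#' @param hist A [peak_histogram()].
#' @param midpoint Stimulus midpoint position in radians (default 0).
#' @param prominence Required mode-to-valley contrast as a fraction of
#'   the histogram maximum (default 0.2; histograms are far noisier than
#'   time-averaged profiles, so this is deliberately larger than the 2
#'   percent used for smooth profiles).
#' @param smooth Circular moving-average half-width in bins (default 1).
#' @param min_n Minimum number of samples for a reliable verdict.
#' @param expected Optional expected mode offsets from the midpoint
#'   (e.g. `c(-dz/2, dz/2)` for a stimulus pair).  When given, the
#'   distribution only counts as resolving the stimuli if each detected
#'   mode lies within `tol` of its expected position; bimodality whose
#'   modes sit elsewhere (for instance at the turning points of a
#'   sloshing bump) is rejected.
#' @param tol Tracking tolerance in radians; defaults to half the
#'   expected offset magnitude, but never below two grid cells.
#' @return A list: `bimodal` (logical), `modes` (positions of the two
#'   side modes, `NA` when absent), `low_confidence` (fewer than `min_n`
#'   samples).
#' @export
two_mode_structure <- function(hist, midpoint = 0, prominence = 0.2,
                               smooth = 1, min_n = 50, expected = NULL,
                               tol = NULL) {
  stopifnot(inherits(hist, "peak_histogram"))
  n <- attr(hist, "n")
  off <- ring_offset(hist$x, midpoint)
  res <- side_mode_test(ring_smooth(hist$count, smooth), off, prominence)
  if (res$bimodal && !is.null(expected)) {
    stopifnot(length(expected) == 2L)
    expected <- sort(expected)
    dxg <- hist$x[2L] - hist$x[1L]
    if (is.null(tol)) tol <- pmax(abs(expected) / 2, 2 * dxg)
    if (any(abs(res$modes - expected) > tol)) res$bimodal <- FALSE
  }
  list(bimodal = res$bimodal, modes = midpoint + res$modes,
       low_confidence = n < min_n)
}

#' Time-averaged firing-rate profile
#'
#' Pointwise mean of the rate field over post-transient samples, the
#' quantity that mimics an electrophysiological tuning-curve
#' measurement.
#'
#' @param sim A `cann_sim`.
#' @return A data frame with columns `x` and `r` of class
#'   `rate_profile`.
#' @export
time_averaged_profile <- function(sim) {
  stopifnot(inherits(sim, "cann_sim"))
  post <- post_transient(sim)
  out <- data.frame(x = sim$grid$x, r = colMeans(sim$r[post, , drop = FALSE]))
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Smallest separation with a bimodal time-averaged profile
#'
#' Given time-averaged profiles for a family of two-stimulus runs with
#' increasing separation, returns the smallest separation whose profile
#' has two interior modes, each exceeding the dip between them by the
#' prominence tolerance (2 percent of the profile maximum by default,
#' enough to suppress discretization ripple on an 80-unit grid).  The
#' split is expected to be monotone in the separation; violations are
#' reported via the returned `bimodal` vector rather than hidden.
#'
#' @param profiles A list of profiles (numeric vectors or
#'   [time_averaged_profile()] frames), one per separation.
#' @param dz The separations, strictly increasing (any units; the return
#'   value uses the same units).
#' @param prominence Mode-to-valley contrast fraction (default 0.02).
#' @return A list: `split` (smallest bimodal separation, `NA` when not
#'   reached), `bimodal` (logical per separation), `monotone`.
#' @export
split_separation <- function(profiles, dz, prominence = 0.02) {
  stopifnot(length(profiles) == length(dz), !is.unsorted(dz, strictly = TRUE))
  bimodal <- vapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    y <- if (is.data.frame(pr)) pr$r else as.numeric(pr)
    off <- if (is.data.frame(pr) && !is.null(pr$x)) ring_offset(pr$x, 0)
           else seq_along(y) - (length(y) + 1) / 2
    side_mode_test(y, off, prominence)$bimodal
  }, logical(1))
  split <- if (any(bimodal)) dz[which(bimodal)[1L]] else NA_real_
  monotone <- !any(diff(bimodal) < 0)
  list(split = split, bimodal = bimodal, monotone = monotone)
}

#' Mean separation and spread of two peak clusters
#'
#' Splits above-threshold peak positions into two clusters and reports
#' the separation of the cluster means and each cluster's standard
#' deviation.  The default rule assigns peaks by the side of the known
#' stimulus midpoint (two-stimulus configurations are placed
#' symmetrically about it); `rule = "kmeans"` uses a 1-D 2-means
#' clustering instead.  A cluster with fewer than 10 samples flags the
#' result as low-confidence rather than failing.
#'
#' @param peaks A data frame from [detect_peaks()].
#' @param midpoint Stimulus midpoint in radians.
#' @param a Excitatory range, used to express results in tuning widths.
#' @param rule `"midpoint"` or `"kmeans"`.
#' @return A list of class `peak_separation`: `separation` (tuning
#'   widths), `sd` (per-cluster SDs, tuning widths), `n` (cluster
#'   sizes), `means` (cluster mean positions, radians),
#'   `low_confidence`.
#' @export
mean_peak_separation <- function(peaks, midpoint = 0, a = 48 * pi / 180,
                                 rule = c("midpoint", "kmeans")) {
  rule <- match.arg(rule)
  tw <- 2 * a
  off <- ring_offset(peaks$position, midpoint)
  if (nrow(peaks) == 0L)
    return(structure(list(separation = NA_real_, sd = c(NA_real_, NA_real_),
                          n = c(0L, 0L), means = c(NA_real_, NA_real_),
                          low_confidence = TRUE),
                     class = "peak_separation"))
  side <- if (rule == "midpoint" || diff(range(off)) == 0) {
    off >= 0
  } else {
    km <- stats::kmeans(off, centers = matrix(range(off), ncol = 1))
    km$cluster == which.max(km$centers)
  }
  m <- c(mean(off[!side]), mean(off[side]))
  s <- c(stats::sd(off[!side]), stats::sd(off[side]))
  n <- c(sum(!side), sum(side))
  structure(list(separation = (m[2] - m[1]) / tw, sd = s / tw, n = n,
                 means = midpoint + m, low_confidence = any(n < 10L)),
            class = "peak_separation")
}

#' @export
print.peak_separation <- function(x, ...) {
  cat(sprintf(
    "Cluster separation: %.3f TW (cluster SDs %.3f / %.3f TW, n = %d / %d)%s\n",
    x$separation, x$sd[1], x$sd[2], x$n[1], x$n[2],
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Perceived-separation curve over stimulus separations
#'
#' Runs one two-stimulus simulation per requested separation (components
#' at `+/- dz/2` about the midpoint, independent seeds) and assembles
#' the mean separation of above-threshold peak clusters, the per-cluster
#' spreads, and the two-mode verdict of the position histogram.
#'
#' @param params A [cann_params()].
#' @param dz Separations in tuning-width units, increasing.
#' @param A,sigma Stimulus strength and relative fluctuation.
#' @param duration,transient Simulation span per separation.
#' @param threshold Peak threshold.
#' @param seed Base seed; run `i` uses `seed + i`.
#' @param grid A [ring_grid()].
#' @param rule Clustering rule, see [mean_peak_separation()].
#' @param mode Peak sampling mode, see [detect_peaks()].
#' @return A data frame of class `resolution_curve` with one row per
#'   separation: `dz`, `separation`, `sd_left`, `sd_right`, `n_left`,
#'   `n_right`, `bimodal`, `low_confidence`.
#' @export
resolution_curve <- function(params, dz, A = 0.8, sigma = 0.3,
                             duration = 20000, transient = 1000,
                             threshold = 6.2, seed = 1,
                             grid = ring_grid(),
                             rule = c("midpoint", "kmeans"),
                             mode = c("sample", "event")) {
  rule <- match.arg(rule); mode <- match.arg(mode)
  tw <- 2 * params$a
  rows <- lapply(seq_along(dz), function(i) {
    d <- dz[i] * tw
    stim <- cann_stimulus(centers = c(-d / 2, d / 2), A = A, sigma = sigma)
    sim <- simulate_cann(params, stim, duration = duration,
                         transient = transient, seed = seed + i, grid = grid)
    pk <- detect_peaks(sim, threshold = threshold, mode = mode)
    sep <- mean_peak_separation(pk, midpoint = 0, a = params$a, rule = rule)
    tm <- two_mode_structure(peak_histogram(pk, grid), midpoint = 0,
                             expected = c(-d / 2, d / 2))
    data.frame(dz = dz[i], separation = sep$separation,
               sd_left = sep$sd[1], sd_right = sep$sd[2],
               n_left = sep$n[1], n_right = sep$n[2],
               bimodal = tm$bimodal, low_confidence = sep$low_confidence)
  })
  out <- do.call(rbind, rows)
  attr(out, "duration") <- duration
  attr(out, "threshold") <- threshold
  class(out) <- c("resolution_curve", "data.frame")
  out
}

#' @export
plot.resolution_curve <- function(x, ...) {
  graphics::plot(x$dz, x$separation, xlab = "stimulus separation (TW)",
                 ylab = "perceived separation (TW)", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Spike positions conditioned on input-bias history
#'
#' For a two-component stimulus, bins each refresh step by the input
#' bias of that step and of the preceding step, and maps the mean
#' above-threshold peak position (in tuning widths) per bin.  Steps with
#' no above-threshold peak are excluded.
#'
#' @param sim A two-stimulus `cann_sim`.
#' @param threshold Peak threshold.
#' @param breaks Bias bin boundaries (default 13 bins over [-0.65,
#'   0.65]).
#' @return A list of class `bias_map`: `bias_mid` (bin centers), `mean_pos`
#'   and `n` (matrices indexed by current-step and previous-step bias bins).
#' @export
bias_conditioned_map <- function(sim, threshold = 6.2,
                                 breaks = seq(-0.65, 0.65, length.out = 14)) {
  stopifnot(inherits(sim, "cann_sim"))
  if (ncol(sim$flucts$delta) != 2L)
    stop("bias conditioning requires a two-component stimulus", call. = FALSE)
  tw <- 2 * sim$params$a
  refresh <- sim$stimulus$refresh
  delta <- sim$flucts$delta
  bias <- input_bias(delta[, 1], delta[, 2])
  step_of <- pmin(floor((sim$times - 1e-9) / refresh) + 1L, length(bias))
  ok <- post_transient(sim) & sim$h >= threshold
  pos_tw <- ring_offset(sim$pos, 0) / tw
  mean_pos_step <- tapply(pos_tw[ok], step_of[ok], mean)
  steps <- as.integer(names(mean_pos_step))
  steps <- steps[steps >= 2L]
  nb <- length(breaks) - 1L
  mp <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  bin <- function(b) pmin(pmax(findInterval(b, breaks), 1L), nb)
  for (s in steps) {
    i <- bin(bias[s]); j <- bin(bias[s - 1L])
    v <- mean_pos_step[as.character(s)]
    cnt[i, j] <- cnt[i, j] + 1L
    mp[i, j] <- if (is.na(mp[i, j])) v else
      mp[i, j] + (v - mp[i, j]) / cnt[i, j]
  }
  structure(list(bias_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 mean_pos = mp, n = cnt),
            class = "bias_map")
}

#' Resolution from short sampling windows
#'
#' Tests whether two overlapping stimuli are resolvable when peak
#' statistics are collected in short windows (matching the duration of a
#' perceptual decision) rather than one long run.  For each separation,
#' a long run is chopped into `n_windows` post-transient windows of
#' `window` time units; the above-threshold peak positions pooled across
#' windows must form two modes tracking the stimulus positions.
#'
#' @param params A [cann_params()].
#' @param dz Separations in tuning-width units, increasing.
#' @param window Window length in synaptic time units (default 500).
#' @param n_windows Number of windows per separation (default 50).
#' @param A,sigma,threshold,seed,grid As in [resolution_curve()].
#' @return A data frame with one row per separation (`dz`, `n_peaks`,
#'   `bimodal`) plus attribute `floor`: the smallest separation from
#'   which the pooled windows stay bimodal through the end of the sweep
#'   (`NA` when never).
#' @export
short_window_resolution <- function(params, dz, window = 500,
                                    n_windows = 50, A = 0.8, sigma = 0.3,
                                    threshold = 6.2, seed = 1,
                                    grid = ring_grid()) {
  stopifnot(!is.unsorted(dz, strictly = TRUE))
  tw <- 2 * params$a
  transient <- 20 * params$tau_d
  duration <- transient + n_windows * window
  rows <- lapply(seq_along(dz), function(i) {
    d <- dz[i] * tw
    stim <- cann_stimulus(centers = c(-d / 2, d / 2), A = A, sigma = sigma)
    sim <- simulate_cann(params, stim, duration = duration,
                         transient = transient, seed = seed + i, grid = grid)
    pk <- detect_peaks(sim, threshold = threshold)
    tm <- two_mode_structure(peak_histogram(pk, grid), midpoint = 0,
                             expected = c(-d / 2, d / 2))
    data.frame(dz = dz[i], n_peaks = nrow(pk), bimodal = tm$bimodal)
  })
  out <- do.call(rbind, rows)
  stable <- rev(cumprod(rev(out$bimodal))) > 0  # bimodal from here onward
  attr(out, "floor") <- if (any(stable)) out$dz[which(stable)[1L]] else NA_real_
  attr(out, "window") <- window
  out
}

#' Resolution floor across a grid of peak thresholds
#'
#' Sweeps stimulus separations once and evaluates, for every threshold
#' of a grid, the smallest separation whose above-threshold
#' peak-position distribution resolves the two stimuli.  Thresholds are
#' taken at quantiles of the pooled peak-height series so the grid
#' spans the run's dynamic range.  A threshold is classified
#' `too_low` when it admits more than `max_frac` of all samples (no
#' selection: background activity swamps the histogram), `sparse` when
#' some separation retains fewer than `min_n` samples, and
#' `intermediate` otherwise.
#'
#' @param params A [cann_params()] (the reference use is the weak-STD
#'   regime, `beta = 0.1`, with `sigma = 0.2`).
#' @param dz Separations in tuning-width units, increasing.
#' @param probs Quantile probabilities defining the threshold grid.
#' @param max_frac Admitted-fraction bound above which a threshold is
#'   `too_low` (default 0.6).
#' @param min_n Minimum sample count per separation (default 50).
#' @param A,sigma,duration,seed,grid As in [resolution_curve()].
#' @return A data frame with one row per threshold: `threshold`,
#'   `admitted_frac`, `band` (`too_low` / `intermediate` / `sparse`),
#'   `floor` (smallest separation that stays resolved through the end
#'   of the sweep, `NA` when never), and one logical column per
#'   separation.
#' @export
threshold_resolution_grid <- function(params, dz,
                                      probs = c(0.05, 0.25, 0.5, 0.75,
                                                0.9, 0.95, 0.98),
                                      max_frac = 0.6, min_n = 50,
                                      A = 0.8, sigma = 0.2,
                                      duration = 20000, seed = 1,
                                      grid = ring_grid()) {
  stopifnot(!is.unsorted(dz, strictly = TRUE))
  tw <- 2 * params$a
  transient <- 20 * params$tau_d
  sims <- lapply(seq_along(dz), function(i) {
    d <- dz[i] * tw
    stim <- cann_stimulus(centers = c(-d / 2, d / 2), A = A, sigma = sigma)
    simulate_cann(params, stim, duration = duration, transient = transient,
                  seed = seed + i, grid = grid)
  })
  h_pool <- unlist(lapply(sims, function(s) s$h[post_transient(s)]))
  thresholds <- unname(stats::quantile(h_pool, probs))
  rows <- lapply(thresholds, function(th) {
    verdict <- vapply(seq_along(dz), function(i) {
      pk <- detect_peaks(sims[[i]], threshold = th)
      if (nrow(pk) < min_n) return(NA)
      d <- dz[i] * tw
      two_mode_structure(peak_histogram(pk, grid), midpoint = 0,
                         expected = c(-d / 2, d / 2))$bimodal
    }, logical(1))
    frac <- mean(h_pool >= th)
    band <- if (frac > max_frac) "too_low"
            else if (anyNA(verdict)) "sparse"
            else "intermediate"
    ok <- !is.na(verdict) & verdict
    stable <- rev(cumprod(rev(ok))) > 0
    fl <- if (band == "intermediate" && any(stable)) dz[which(stable)[1L]]
          else NA_real_
    cbind(data.frame(threshold = th, admitted_frac = frac, band = band,
                     floor = fl),
          stats::setNames(as.data.frame(t(verdict)), paste0("dz_", dz)))
  })
  do.call(rbind, rows)
}
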