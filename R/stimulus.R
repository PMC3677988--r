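#' Multi-component fluctuating stimulus
#'
#' Describes an external input made of `n` Gaussian components with
#' independently fluctuating amplitudes.  Component amplitudes are
#' `1 + delta_i` in units of the mean component amplitude; the relative
#' fluctuations `delta_i` are redrawn i.i.d. Normal(0, `sigma`^2) every
#' `refresh` time units and held constant in between (zero-order hold).
#' The combined profile is max-normalized to amplitude `A` at every
#' instant, so only the ratio `sigma` of fluctuation to mean matters.
#'
#' @param centers Component peak positions in radians.
#' @param A Rescaled maximum input strength (>= 0; 0 disables the input).
#' @param sigma Relative fluctuation amplitude `sigma_A / A_0` (>= 0).
#' @param a_I Component width in radians, or `NULL` to use the model's
#'   `a_I` at simulation time.
#' @param refresh Interval between fluctuation redraws in synaptic time
#'   units (default 50).
#' @return An object of class `cann_stimulus`.
#' @examples
#' two_stim <- cann_stimulus(centers = c(-0.5, 0.5), A = 0.8, sigma = 0.3)
#' @export
cann_stimulus <- function(centers, A = 0.8, sigma = 0.3, a_I = NULL,
                          refresh = 50) {
  stopifnot(is.numeric(centers), length(centers) >= 1L,
            is.numeric(A), length(A) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(refresh), length(refresh) == 1L)
  if (A < 0) stop("'A' must be nonnegative", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be nonnegative", call. = FALSE)
  if (refresh <= 0) stop("'refresh' must be positive", call. = FALSE)
  if (!is.null(a_I)) stopifnot(is.numeric(a_I), length(a_I) == 1L, a_I > 0)
  structure(list(centers = as.numeric(centers), A = A, sigma = sigma,
                 a_I = a_I, refresh = refresh),
            class = "cann_stimulus")
}

#' @export
print.cann_stimulus <- function(x, ...) {
  cat(sprintf(
    "Stimulus: %d component(s) at {%s} rad, A = %.3g, sigma/A0 = %.3g, refresh every %g tau_s\n",
    length(x$centers), paste(signif(x$centers, 4), collapse = ", "),
    x$A, x$sigma, x$refresh))
  invisible(x)
}

#' Draw a piecewise-constant fluctuation sequence
#'
#' Draws the relative amplitude fluctuations for `n_steps` refresh
#' intervals, one independent Normal(0, `sigma`^2) value per component
#' and step.  Uses the current R random-number state, so results are
#' deterministic after `set.seed()`.  Fluctuations are deliberately not
#' clipped: a single component amplitude may go negative (an event with
#' probability ~4e-4 per draw at `sigma = 0.3`); clipping would bias the
#' mean input upward.
#'
#' @param stimulus A [cann_stimulus()].
#' @param n_steps Number of refresh intervals (>= 1).
#' @return An object of class `fluctuation_log`: a list with `step_times`
#'   (redraw instants, starting at 0), `delta` (an `n_steps x n` matrix
#'   of relative fluctuations) and `refresh`.
#' @export
draw_fluctuations <- function(stimulus, n_steps) {
  stopifnot(inherits(stimulus, "cann_stimulus"),
            is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1)
  n_steps <- as.integer(n_steps)
  n <- length(stimulus$centers)
  delta <- if (stimulus$sigma > 0) {
    matrix(stats::rnorm(n_steps * n, 0, stimulus$sigma),
           nrow = n_steps, ncol = n, byrow = TRUE)
  } else {
    matrix(0, n_steps, n)
  }
  structure(list(step_times = (seq_len(n_steps) - 1L) * stimulus$refresh,
                 delta = delta, refresh = stimulus$refresh),
            class = "fluctuation_log")
}

#' Raw multi-component input profile
#'
#' Evaluates the unnormalized stimulus profile
#' `I0_i = sum_c (1 + delta_c) * exp(-d(x_i, z_c)^2 / (2 a_I^2))`
#' (in units of the mean component amplitude) on the grid, with periodic
#' distances to each component center.
#'
#' @param grid A [ring_grid()].
#' @param stimulus A [cann_stimulus()].
#' @param delta Relative fluctuations, one per component.
#' @param a_I Component width; overrides the stimulus setting.
#' @return A length-`N` field.
#' @export
input_profile <- function(grid, stimulus, delta = rep(0, length(stimulus$centers)),
                          a_I = NULL) {
  stopifnot(inherits(grid, "ring_grid"), inherits(stimulus, "cann_stimulus"))
  if (length(delta) != length(stimulus$centers))
    stop("'delta' must have one entry per stimulus component", call. = FALSE)
  w <- a_I %||% stimulus$a_I
  if (is.null(w))
    stop("no component width: set 'a_I' on the stimulus or pass it here",
         call. = FALSE)
  E <- vapply(stimulus$centers,
              function(z) exp(-ring_distance(grid$x, z, grid$L)^2 / (2 * w^2)),
              numeric(grid$N))
  as.numeric(E %*% (1 + delta))
}

#' Max-normalize an input profile
#'
#' Scales a raw profile so that its maximum over the grid equals the
#' fixed input strength `A`, modelling an input whose peak magnitude is
#' invariant under component fluctuations.
#'
#' @param I0 Raw input field.
#' @param A Target maximum (> 0).
#' @return The rescaled field, with `max(.) == A` exactly.
#' @export
normalize_input <- function(I0, A) {
  m <- max(I0)
  if (!is.finite(m) || m <= 0)
    stop("degenerate input: profile maximum is not positive", call. = FALSE)
  A * (I0 / m)
}

#' Instantaneous input bias between two components
#'
#' The relative advantage of the first of two stimulus components,
#' `(delta1 - delta2) / max(1 + delta1, 1 + delta2)` with amplitudes in
#' units of the mean component amplitude.  Antisymmetric under component
#' swap.
#'
#' @param delta1,delta2 Relative fluctuations of the two components.
#' @return Dimensionless bias (vectorized).
#' @export
input_bias <- function(delta1, delta2) {
  den <- pmax(1 + delta1, 1 + delta2)
  if (any(den <= 0))
    stop("degenerate input: both component amplitudes are nonpositive",
         call. = FALSE)
  (delta1 - delta2) / den
}

#' Read and write fluctuation logs
#'
#' A fluctuation log serializes to a plain-text table with a `time`
#' column and one `delta_<i>` column per component; replaying a log
#' through [simulate_cann()] reproduces a run exactly.
#'
#' @param log A `fluctuation_log`.
#' @param path File path.
#' @return `write_fluctuation_log()` returns `path` invisibly;
#'   `read_fluctuation_log()` returns a `fluctuation_log`.
#' @export
write_fluctuation_log <- function(log, path) {
  stopifnot(inherits(log, "fluctuation_log"))
  df <- data.frame(time = log$step_times, log$delta)
  names(df) <- c("time", paste0("delta_", seq_len(ncol(log$delta))))
  df[] <- lapply(df, function(col) sprintf("%.17g", col))  # bit-exact replay
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fluctuation_log
#' @export
read_fluctuation_log <- function(path) {
  df <- utils::read.csv(path)
  delta <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(delta) <- NULL
  refresh <- if (nrow(df) > 1L) df$time[2L] - df$time[1L] else NA_real_
  structure(list(step_times = df$time, delta = delta, refresh = refresh),
            class = "fluctuation_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
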