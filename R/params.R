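#' Parameters of the recurrent ring model
#'
#' All parameters are the dimensionless rescaled ones: the raw neuron
#' density, coupling strength, inhibition and depression rates enter only
#' through these combinations.  `k` is the inhibition strength relative to
#' the critical value above which no self-sustained bump exists; `beta` is
#' the rescaled depression strength; times are in units of the synaptic
#' time constant.
#'
#' @param k Rescaled divisive-inhibition strength (>= 0; a bump attractor
#'   exists without input only for `k <= 1`).
#' @param beta Rescaled short-term-depression strength (>= 0; `beta = 0`
#'   disables depression).
#' @param a Excitatory interaction range in radians (default 48 degrees,
#'   i.e. tuning width 96 degrees).
#' @param a_I Stimulus component width in radians (defaults to `a`).
#' @param tau_d Neurotransmitter recovery time constant in units of the
#'   synaptic time constant (default 50).
#' @param inhibition `"global"` (divisive pool over the whole ring) or
#'   `"local"` (Gaussian-weighted pool of range `b`).
#' @param b Local-inhibition range in radians; required in local mode and
#'   must exceed `a`.
#' @param b_prefactor Normalization of the local-inhibition kernel:
#'   `"flat"` (kernel maximum 1; recovers the global model as `b` grows)
#'   or `"gaussian"` (kernel scaled by `1/(sqrt(2*pi)*b)`).  The model
#'   variant leaves this choice open, so it is exposed rather than fixed.
#' @return An object of class `cann_params`.
#' @examples
#' cann_params()                      # spiking-regime defaults
#' cann_params(beta = 0)              # no short-term depression
#' @export
cann_params <- function(k = 0.5, beta = 0.24, a = 48 * pi / 180, a_I = a,
                        tau_d = 50, inhibition = c("global", "local"),
                        b = NULL, b_prefactor = c("flat", "gaussian")) {
  inhibition <- match.arg(inhibition)
  b_prefactor <- match.arg(b_prefactor)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(a_I), length(a_I) == 1L, a_I > 0,
            is.numeric(tau_d), length(tau_d) == 1L, tau_d > 0)
  if (inhibition == "local") {
    if (is.null(b) || !is.numeric(b) || length(b) != 1L || b <= a)
      stop("local inhibition requires a range 'b' larger than 'a'",
           call. = FALSE)
  } else {
    b <- NULL
  }
  structure(list(k = k, beta = beta, a = a, a_I = a_I, tau_d = tau_d,
                 inhibition = inhibition, b = b, b_prefactor = b_prefactor),
            class = "cann_params")
}

#' @export
print.cann_params <- function(x, ...) {
  cat(sprintf(
    "Recurrent CANN parameters: k = %.3g, beta = %.3g, a = %.4g rad (%.3g deg),\n",
    x$k, x$beta, x$a, rad_to_deg(x$a)))
  cat(sprintf("  a_I = %.4g rad, tau_d = %g tau_s, %s inhibition",
              x$a_I, x$tau_d, x$inhibition))
  if (x$inhibition == "local")
    cat(sprintf(" (b = %.4g rad, %s prefactor)", x$b, x$b_prefactor))
  cat("\n")
  invisible(x)
}

#' Parameters of the purely feedforward model variant
#'
#' A control architecture without recurrence: the current is driven by a
#' difference-of-Gaussians filter of the (depressed) input, depression is
#' driven by the input itself, and the rate is linear above threshold.
#' The rescaled input amplitude is carried by the stimulus object.
#'
#' @param JI Inhibitory-to-excitatory coupling ratio (must be < 1).
#' @param a Excitatory range in radians.
#' @param b Inhibitory range in radians (must exceed `a`; default `3*a`).
#' @param beta Rescaled depression strength (default 0.2).
#' @param tau_d Recovery time constant in synaptic time units.
#' @param a_I Stimulus component width (defaults to `a`).
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(JI = 0.3, a = 48 * pi / 180, b = 3 * a, beta = 0.2,
                      tau_d = 50, a_I = a) {
  stopifnot(is.numeric(JI), length(JI) == 1L, JI >= 0,
            is.numeric(a), a > 0, is.numeric(b), is.numeric(beta), beta >= 0,
            is.numeric(tau_d), tau_d > 0)
  if (JI >= 1) stop("'JI' must be < 1 (excitation dominates)", call. = FALSE)
  if (b <= a) stop("'b' must exceed 'a' (broader inhibition)", call. = FALSE)
  structure(list(JI = JI, a = a, b = b, beta = beta, tau_d = tau_d, a_I = a_I),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat(sprintf(
    "Feedforward parameters: J_I/J_E = %.3g, a = %.4g rad, b = %.4g rad, beta = %.3g, tau_d = %g\n",
    x$JI, x$a, x$b, x$beta, x$tau_d))
  invisible(x)
}

#' Stationary bump of the depression-free network
#'
#' Closed-form height of the self-sustained Gaussian bump of the rescaled
#' network without input and without depression, valid for `0 < k <= 1`:
#' current height `u0 = 2*sqrt(2)*(1 + sqrt(1 - k))/k` and rate height
#' `r0 = u0^2 / (1 + k*u0^2/8)`.  The bump current profile has standard
#' deviation `sqrt(2)*a`; the rate profile, `a`.  Used as the reference
#' activity scale when classifying dynamical regimes.
#'
#' @param k Rescaled inhibition strength in `(0, 1]`.
#' @return A list with elements `u0` and `r0`.
#' @export
bump_heights <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k <= 0 || k > 1)
    stop("a self-sustained bump exists only for 0 < k <= 1", call. = FALSE)
  u0 <- 2 * sqrt(2) * (1 + sqrt(1 - k)) / k
  list(u0 = u0, r0 = u0^2 / (1 + k * u0^2 / 8))
}
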