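#' Divisive inhibition pool
#'
#' The denominator of the firing-rate nonlinearity.  In global mode it is
#' the scalar `B = 1 + k/(8*sqrt(2*pi)*a) * sum_j dx * u_j^2`; in local
#' mode each unit pools the squared current through a Gaussian of range
#' `b`, giving a field `B_i >= 1`.
#'
#' @param u Current field (length `N`).
#' @param grid A [ring_grid()].
#' @param params A [cann_params()].
#' @return A scalar (global inhibition) or a length-`N` vector (local).
#' @export
divisive_inhibition <- function(u, grid, params) {
  pref <- params$k / (8 * sqrt(2 * pi) * params$a)
  if (params$inhibition == "global") {
    1 + pref * sum(u^2) * grid$dx
  } else {
    kb <- ring_gauss_matrix(grid, params$b)
    if (params$b_prefactor == "gaussian")
      kb <- kb / (sqrt(2 * pi) * params$b)
    as.numeric(1 + pref * grid$dx * (kb %*% u^2))
  }
}

#' Divisively inhibited firing rate
#'
#' Rescaled population firing rate `r = u^2 / B` for positive currents and
#' zero otherwise (the rate at exactly `u = 0` is zero).
#'
#' @param u Current field.
#' @param B Divisive inhibition, a scalar or a field (all entries >= 1).
#' @return Nonnegative rate field of the same length as `u`.
#' @export
firing_rate <- function(u, B) {
  if (any(B < 1)) stop("divisive inhibition must be >= 1", call. = FALSE)
  pmax(u, 0)^2 / B
}

#' Time derivatives of the recurrent model
#'
#' Right-hand side of the rescaled field equations: the current decays,
#' is driven by the external input and by the depression-weighted
#' recurrent drive; the available neurotransmitter fraction recovers
#' towards 1 and is consumed in proportion to the local rate.
#'
#' @param u,p Current and neurotransmitter fields (length `N`).
#' @param I_ext Rescaled external input field (output of
#'   [normalize_input()]).
#' @param params A [cann_params()].
#' @param kernel Coupling matrix from [excitatory_kernel()] built on the
#'   same grid.
#' @param grid A [ring_grid()].
#' @return A list with elements `du` and `dp` (time derivatives in
#'   synaptic time units).
#' @export
cann_rhs <- function(u, p, I_ext, params, kernel, grid) {
  N <- grid$N
  if (length(u) != N || length(p) != N || length(I_ext) != N ||
      nrow(kernel) != N || ncol(kernel) != N)
    stop("field/kernel dimensions do not match the grid", call. = FALSE)
  B <- divisive_inhibition(u, grid, params)
  r <- firing_rate(u, B)
  list(du = -u + I_ext + as.numeric(kernel %*% (p * r)),
       dp = (-p + 1 - params$beta * p * r) / params$tau_d)
}

#' Time derivatives of the feedforward model
#'
#' In the purely feedforward variant the current is driven by the
#' difference-of-Gaussians filtered, depression-weighted input; the
#' depression variable is consumed by the input itself (not the rate);
#' and the rate is linear above threshold, `r = max(u, 0)`.
#'
#' @param u,p Current and neurotransmitter fields.
#' @param I_ext Rescaled input field.
#' @param params An [ff_params()].
#' @param kernel Matrix from [feedforward_kernel()].
#' @param grid A [ring_grid()].
#' @return A list with elements `du` and `dp`.
#' @export
ff_rhs <- function(u, p, I_ext, params, kernel, grid) {
  N <- grid$N
  if (length(u) != N || length(p) != N || length(I_ext) != N)
    stop("field dimensions do not match the grid", call. = FALSE)
  list(du = -u + as.numeric(kernel %*% (p * I_ext)),
       dp = (-p + 1 - params$beta * p * I_ext) / params$tau_d)
}
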