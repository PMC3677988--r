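#' Discretized periodic stimulus space
#'
#' Builds a uniform grid of `N` preferred-stimulus positions on a ring of
#' circumference `L`.  Positions span `[-L/2, L/2)`; the boundary is
#' periodic.  The default, `N = 80` units on a 360-degree ring, is the
#' standard network configuration used throughout the package.
#'
#' @param N Number of units (positive integer, at least 4).
#' @param L Ring circumference in radians (default `2*pi`, i.e. 360 degrees).
#' @return An object of class `ring_grid`: a list with elements `N`, `L`,
#'   `x` (positions) and `dx` (spacing, `L/N`).
#' @examples
#' g <- ring_grid()
#' g$dx            # 2*pi/80
#' @export
ring_grid <- function(N = 80L, L = 2 * pi) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 4 || N != round(N))
    stop("'N' must be a single integer >= 4", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop("'L' must be a single positive number", call. = FALSE)
  N <- as.integer(N)
  dx <- L / N
  structure(list(N = N, L = L, x = -L / 2 + dx * (seq_len(N) - 1L), dx = dx),
            class = "ring_grid")
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("Ring grid: %d units on [%.4g, %.4g), dx = %.4g rad (%.3g deg)\n",
              x$N, -x$L / 2, x$L / 2, x$dx, x$dx * 180 / pi))
  invisible(x)
}

#' Minimal-image distance on the ring
#'
#' Shortest angular distance between positions on a periodic domain of
#' circumference `L`.  Vectorized over both arguments.
#'
#' @param x1,x2 Positions in radians.
#' @param L Ring circumference (default `2*pi`).
#' @return Distances in `[0, L/2]`.
#' @export
ring_distance <- function(x1, x2, L = 2 * pi) {
  d <- abs(x1 - x2) %% L
  pmin(d, L - d)
}

## Signed minimal-image offset x - ref, wrapped into (-L/2, L/2].
ring_offset <- function(x, ref, L = 2 * pi) {
  d <- (x - ref) %% L
  ifelse(d > L / 2, d - L, d)
}

## Unnormalized Gaussian interaction matrix exp(-d_ij^2 / (2 w^2)).
ring_gauss_matrix <- function(grid, w) {
  D <- outer(grid$x, grid$x, ring_distance, L = grid$L)
  exp(-D^2 / (2 * w^2))
}

#' Recurrent excitatory coupling matrix
#'
#' Discretized translation-invariant Gaussian coupling on the ring,
#' `W[i, j] = dx / (sqrt(2*pi) * a) * exp(-d(x_i, x_j)^2 / (2 a^2))`,
#' with minimal-image periodic distances.  In the rescaled equations the
#' recurrent drive on unit `i` is `sum_j W[i, j] * p_j * r_j`.
#'
#' @param grid A [ring_grid()].
#' @param a Excitatory interaction range in radians.
#' @return An `N x N` symmetric circulant matrix of nonnegative weights.
#' @export
excitatory_kernel <- function(grid, a) {
  stopifnot(inherits(grid, "ring_grid"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  grid$dx / (sqrt(2 * pi) * a) * ring_gauss_matrix(grid, a)
}

#' Feedforward difference-of-Gaussians kernel
#'
#' Excitatory-minus-inhibitory coupling of the purely feedforward model
#' variant:
#' `K[i, j] = dx * (exp(-d^2/(2 a^2)) - (J_I/J_E) * exp(-d^2/(2 b^2)))`
#' with `b > a` and `J_I < J_E`.  The Gaussians carry no
#' `1/(sqrt(2*pi)*a)` normalization (the feedforward couplings are
#' defined bare); the `dx` factor makes `sum_j K[i, j] * p_j * I_j`
#' approximate the ring integral of the filtered input, so that with the
#' input amplitude expressed in density-times-coupling units the current
#' is parameter-closed and the reference peak threshold of 0.45 applies.
#'
#' @param grid A [ring_grid()].
#' @param params An [ff_params()] object.
#' @return An `N x N` matrix.
#' @export
feedforward_kernel <- function(grid, params) {
  stopifnot(inherits(grid, "ring_grid"), inherits(params, "ff_params"))
  grid$dx * (ring_gauss_matrix(grid, params$a) -
             params$JI * ring_gauss_matrix(grid, params$b))
}

#' Angle conversions
#'
#' Helpers to convert between degrees, radians and tuning-width units.
#' The tuning width (TW) is twice the excitatory range, `TW = 2*a`
#' (96 degrees in the default configuration).
#'
#' @param deg,rad,tw Angles in the named unit.
#' @param a Excitatory range in radians (defines the tuning width).
#' @return The converted angle(s).
#' @export
deg_to_rad <- function(deg) deg * pi / 180

#' @rdname deg_to_rad
#' @export
rad_to_deg <- function(rad) rad * 180 / pi

#' @rdname deg_to_rad
#' @export
tw_to_rad <- function(tw, a) tw * 2 * a

#' @rdname deg_to_rad
#' @export
rad_to_tw <- function(rad, a) rad / (2 * a)
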