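#' Deterministic test fixtures
#'
#' Generates small, fully deterministic assets for fast tests and
#' regression checks:
#'
#' * `"mini"` -- a 16-unit grid, spiking-regime parameters, a frozen
#'   two-component fluctuation log (seed 421, 20 refresh steps) and the
#'   short trajectory simulated from them.
#' * `"gauss-mix"` -- analytic two-Gaussian profiles (unit width `a`)
#'   over a grid of separations, whose bimodality split is exactly at
#'   `2a`; the reference family for [split_separation()].
#' * `"ref-run"` -- a 1000 tau_s reference run at the standard
#'   parameters plus a numeric signature (sums and extrema of the
#'   sampled fields) that must reproduce bit-identically across
#'   invocations.
#'
#' @param name Fixture name.
#' @param dir Optional directory; when given, plain-text copies of the
#'   fixture tables are written there.
#' @return The fixture object (a list; contents depend on `name`).
#' @export
make_fixture <- function(name = c("mini", "gauss-mix", "ref-run"),
                         dir = NULL) {
  name <- match.arg(name)
  fx <- switch(name, mini = fixture_mini(), `gauss-mix` = fixture_gauss_mix(),
               `ref-run` = fixture_ref_run())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(fx$sim)) write_trajectory(fx$sim, file.path(dir, name))
    if (!is.null(fx$profiles)) {
      m <- do.call(cbind, lapply(fx$profiles, function(p) p$r))
      colnames(m) <- paste0("dz_", fx$dz)
      utils::write.csv(cbind(x = fx$profiles[[1]]$x, m),
                       file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    }
    if (!is.null(fx$signature))
      jsonlite::write_json(fx$signature,
                           file.path(dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA)
  }
  fx
}

fixture_mini <- function() {
  grid <- ring_grid(N = 16L)
  params <- cann_params()
  stim <- cann_stimulus(centers = c(-0.4, 0.4), A = 0.8, sigma = 0.3)
  set.seed(421)
  flucts <- draw_fluctuations(stim, 20L)
  sim <- simulate_cann(params, stim, duration = 1000, transient = 500,
                       flucts = flucts, grid = grid)
  list(grid = grid, params = params, stimulus = stim, flucts = flucts,
       sim = sim)
}

fixture_gauss_mix <- function(a = 48 * pi / 180) {
  grid <- ring_grid()
  dz <- seq(0.5, 1.5, by = 0.125)  # tuning widths; split at exactly 1 TW
  profiles <- lapply(dz, function(d) {
    z <- d * a  # half-separation = dz * TW / 2 = dz * a
    y <- exp(-ring_distance(grid$x, z, grid$L)^2 / (2 * a^2)) +
         exp(-ring_distance(grid$x, -z, grid$L)^2 / (2 * a^2))
    structure(data.frame(x = grid$x, r = y),
              class = c("rate_profile", "data.frame"))
  })
  list(dz = dz, profiles = profiles, a = a)
}

fixture_ref_run <- function() {
  sim <- simulate_cann(cann_params(),
                       cann_stimulus(centers = c(-0.5, 0.5), A = 0.8,
                                     sigma = 0.3),
                       duration = 1000, transient = 500, seed = 2024)
  signature <- list(sum_u = sum(sim$u), sum_p = sum(sim$p),
                    sum_r = sum(sim$r), max_h = max(sim$h),
                    final_u = sim$u[nrow(sim$u), 1L])
  list(sim = sim, signature = signature)
}
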