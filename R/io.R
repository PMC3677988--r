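#' Read an experiment configuration
#'
#' Loads a nested YAML configuration describing a full experiment:
#' a `model` section (recurrent parameters, or feedforward ones under
#' `variant: feedforward`), a `stimulus` section, a `simulation` section
#' and an optional `analysis` section.  Angle-valued keys accept a unit
#' suffix in the value string: `"48 deg"`, `"0.8378 rad"` or `"0.5 tw"`
#' (tuning widths, resolved against the model's `a`).  Unknown keys in
#' any section raise a schema error naming them.
#'
#' The simulation section's grid size key is `n_units`
#' (a bare `N` would be parsed as boolean by YAML).
#'
#' @param path Path to a YAML file.
#' @return A list of class `cann_config` with elements `params`,
#'   `stimulus`, `simulation` (argument list for [simulate_cann()]) and
#'   `analysis`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("model", "stimulus", "simulation", "analysis", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  ## exact [[ ]] access throughout: $ would partial-match keys like
  ## "b" against "beta" or "a" against "a_I"
  model <- raw[["model"]] %||% list()
  variant <- model[["variant"]] %||% "recurrent"
  model[["variant"]] <- NULL
  a <- parse_angle(model[["a"]] %||% (48 * pi / 180), NA)
  parse_ang <- function(v) if (is.null(v)) NULL else parse_angle(v, a)

  if (identical(variant, "feedforward")) {
    check_keys(model, c("JI", "a", "b", "beta", "tau_d", "a_I"), "model")
    params <- ff_params(JI = model[["JI"]] %||% 0.3, a = a,
                        b = parse_ang(model[["b"]]) %||% (3 * a),
                        beta = model[["beta"]] %||% 0.2,
                        tau_d = model[["tau_d"]] %||% 50,
                        a_I = parse_ang(model[["a_I"]]) %||% a)
  } else {
    check_keys(model, c("k", "beta", "a", "a_I", "tau_d", "inhibition",
                        "b", "b_prefactor"), "model")
    params <- cann_params(k = model[["k"]] %||% 0.5,
                          beta = model[["beta"]] %||% 0.24,
                          a = a, a_I = parse_ang(model[["a_I"]]) %||% a,
                          tau_d = model[["tau_d"]] %||% 50,
                          inhibition = model[["inhibition"]] %||% "global",
                          b = parse_ang(model[["b"]]),
                          b_prefactor = model[["b_prefactor"]] %||% "flat")
  }

  st <- raw[["stimulus"]] %||% list()
  check_keys(st, c("centers", "A", "sigma", "a_I", "refresh"), "stimulus")
  stim <- cann_stimulus(
    centers = vapply(as.list(st[["centers"]] %||% 0), parse_angle,
                     numeric(1), a = a),
    A = st[["A"]] %||% 0.8, sigma = st[["sigma"]] %||% 0.3,
    a_I = parse_ang(st[["a_I"]]), refresh = st[["refresh"]] %||% 50)

  si <- raw[["simulation"]] %||% list()
  check_keys(si, c("duration", "sample_interval", "transient", "seed",
                   "rtol", "atol", "method", "n_units", "L"), "simulation")
  simulation <- list(duration = si[["duration"]] %||% 2000,
                     sample_interval = si[["sample_interval"]] %||% 1,
                     transient = si[["transient"]] %||% 1000,
                     seed = si[["seed"]], rtol = si[["rtol"]] %||% 1e-6,
                     atol = si[["atol"]] %||% 1e-6,
                     method = si[["method"]] %||% "rk45dp7",
                     grid = ring_grid(N = si[["n_units"]] %||% 80L,
                                      L = si[["L"]] %||% (2 * pi)))

  an <- raw[["analysis"]] %||% list()
  check_keys(an, c("threshold", "rule", "mode", "prominence"), "analysis")
  analysis <- list(threshold = an[["threshold"]] %||%
                     (if (identical(variant, "feedforward")) 0.45 else 6.2),
                   rule = an[["rule"]] %||% "midpoint",
                   mode = an[["mode"]] %||% "sample",
                   prominence = an[["prominence"]] %||% 0.2)

  structure(list(params = params, stimulus = stim, simulation = simulation,
                 analysis = analysis, output = raw[["output"]]),
            class = "cann_config")
}

check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in '%s' section: %s", section,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

## Accepts a number (radians) or a string "value unit" with unit one of
## deg / rad / tw.
parse_angle <- function(v, a) {
  if (is.numeric(v)) return(v)
  m <- regmatches(v, regexec("^\\s*(-?[0-9.eE+-]+)\\s*(deg|rad|tw)\\s*$", v))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse angle '%s' (use e.g. '48 deg', '0.5 tw')", v),
         call. = FALSE)
  val <- as.numeric(m[2L])
  switch(m[3L],
         deg = deg_to_rad(val),
         rad = val,
         tw = {
           if (is.na(a)) stop("'tw' units need the model range 'a'",
                              call. = FALSE)
           tw_to_rad(val, a)
         })
}

#' Run a configured experiment
#'
#' Simulates a [read_experiment_config()] experiment and writes the
#' trajectory tables, the above-threshold peak samples, the
#' max-normalized position histogram and a JSON summary into `outdir`.
#' The directory then contains everything needed to [replay()] the run
#' exactly.
#'
#' @param config A `cann_config` or a path to a YAML file.
#' @param outdir Output directory.
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(config, outdir) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "cann_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("cannstd %s | seed=%s rtol=%g atol=%g N=%d",
                  as.character(utils::packageVersion("cannstd")),
                  format(config$simulation$seed %||% "none"),
                  config$simulation$rtol, config$simulation$atol,
                  config$simulation$grid$N))
  t0 <- proc.time()[["elapsed"]]
  sim <- do.call(simulate_cann,
                 c(list(params = config$params, stimulus = config$stimulus),
                   config$simulation))
  write_trajectory(sim, outdir)
  pk <- detect_peaks(sim, threshold = config$analysis$threshold,
                     mode = config$analysis$mode)
  utils::write.csv(pk, file.path(outdir, "peaks.csv"), row.names = FALSE)
  hist <- peak_histogram(pk, sim$grid)
  utils::write.csv(as.data.frame(hist), file.path(outdir, "histogram.csv"),
                   row.names = FALSE)
  regime <- classify_regime(sim)
  smry <- list(regime = regime$label,
               diagnostics = as.list(regime$diagnostics),
               n_peaks = nrow(pk),
               threshold = config$analysis$threshold,
               elapsed_s = proc.time()[["elapsed"]] - t0)
  if (length(config$stimulus$centers) == 2L) {
    sep <- mean_peak_separation(pk,
      midpoint = mean(ring_offset(config$stimulus$centers, 0)),
      a = config$params$a, rule = config$analysis$rule)
    smry$separation_tw <- sep$separation
    smry$cluster_sd_tw <- sep$sd
  }
  jsonlite::write_json(smry, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("run complete in %.1f s: regime %s, %d peaks above %.3g",
                  smry$elapsed_s, smry$regime, smry$n_peaks, smry$threshold))
  invisible(smry)
}
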