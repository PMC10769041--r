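#' @name experiments
#' @title Desk-scale reproducible experiments
#'
#' @description
#' `run_experiment()` executes one named, fully deterministic analysis at a
#' reduced desk-scale grid and writes its results as tidy CSV plus a JSON
#' metadata sidecar (grid specification, Pade order, tolerances, step size,
#' package version). CSV is the artifact of record; plotting is left to the
#' caller. Every experiment is rerun-identical: there is no randomness
#' anywhere in the pipeline.
#'
#' Available experiments (see `list_experiments()`):
#' \describe{
#'   \item{nyquist_sweep}{Nyquist curves while increasing delay, then
#'     proportional gain, then integral gain.}
#'   \item{stability_field}{Boolean stability over a (kp, ki, td) lattice.}
#'   \item{dividing_surface}{Maximum stable delay per gain pair.}
#'   \item{stability_slice}{Stable-region boundary in the gain plane at the
#'     fly's 20 ms delay.}
#'   \item{hybrid_bounds}{Peak-to-peak response bound over the gain space at
#'     several switching thresholds, 2 Hz / 50 deg/s stimulus.}
#'   \item{continuous_error}{Continuous-system SAE over the gain space and
#'     frequency.}
#'   \item{sigma_map}{Optimal switching threshold across the gain space per
#'     frequency, with the continuous-optimal fraction.}
#'   \item{error_surface_fly, error_surface_mid, error_surface_high}{SAE over
#'     (sigma, frequency) at the fly pair (10, 1), a mid pair (18, 500), and
#'     a high-gain pair (60, 700).}
#'   \item{margins}{Gain/phase margins for the fly pair and the high-gain
#'     pair.}
#'   \item{demo_traces}{Hybrid time traces at increasing sigma for a
#'     demonstration system.}
#'   \item{adjusted_sigma_traces}{Time traces at hand-adjusted thresholds
#'     showing delay compensation and resonance bounding.}
#' }
NULL

experiment_registry <- function() {
  list(
    nyquist_sweep = exp_nyquist_sweep,
    stability_field = exp_stability_field,
    dividing_surface = exp_dividing_surface,
    stability_slice = exp_stability_slice,
    hybrid_bounds = exp_hybrid_bounds,
    continuous_error = exp_continuous_error,
    sigma_map = exp_sigma_map,
    error_surface_fly = exp_error_surface_fly,
    error_surface_mid = exp_error_surface_mid,
    error_surface_high = exp_error_surface_high,
    margins = exp_margins,
    demo_traces = exp_demo_traces,
    adjusted_sigma_traces = exp_adjusted_sigma_traces
  )
}

#' List the available experiments
#' @return Character vector of experiment names.
#' @export
list_experiments <- function() names(experiment_registry())

#' Run a named experiment
#'
#' @param name Experiment name (see [list_experiments()]).
#' @param out_dir Output directory (created if missing); default a
#'   per-experiment subdirectory of `tempdir()`.
#' @param overrides Named list overriding the experiment's default
#'   parameters (unknown names are an error).
#' @return Invisibly, the result table(s); side effect: `<name>.csv` and
#'   `<name>_meta.json` under `out_dir`.
#' @examples
#' \donttest{
#' run_experiment("margins")
#' }
#' @export
run_experiment <- function(name, out_dir = file.path(tempdir(), name),
                           overrides = list()) {
  reg <- experiment_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown experiment '", paste(name, collapse = ","),
         "'; see list_experiments()")
  fn <- reg[[name]]
  defaults <- formals(fn)$defaults
  defaults <- eval(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("invalid override(s) for experiment '", name, "': ",
         paste(bad, collapse = ", "))
  pars <- modifyList(defaults, overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- fn(defaults = pars)
  write.csv(tab, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  meta <- list(experiment = name, parameters = pars,
               package_version = as.character(utils::packageVersion("hybridgaze")),
               rows = nrow(tab))
  jsonlite::write_json(meta, file.path(out_dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(tab)
}

exp_nyquist_sweep <- function(defaults = list(
    cu = 4.2, omega = pracma::logseq(1e-2, 500, 800),
    sets = list(c(10, 200, 0.040), c(10, 200, 0.050), c(10, 200, 0.065),
                c(10, 200, 0.020), c(25, 200, 0.020), c(45, 200, 0.020),
                c(10, 280, 0.020), c(10, 360, 0.020)))) {
  p <- defaults
  do.call(rbind, lapply(p$sets, function(s) {
    nc <- nyquist_curve(controller_gains(s[1], s[2]), plant_params(p$cu),
                        delay_model(td = s[3]), omega = p$omega)
    data.frame(kp_star = s[1], ki_star = s[2], td = s[3], omega = nc$omega,
               re = Re(nc$response), im = Im(nc$response))
  }))
}

exp_stability_field <- function(defaults = list(
    cu = 4.2, kp_axis = seq(2, 60, length.out = 15),
    ki_axis = seq(2, 900, length.out = 15),
    td_axis = seq(0.005, 0.08, length.out = 8))) {
  p <- defaults
  stability_field(p$kp_axis, p$ki_axis, p$td_axis, plant_params(p$cu))
}

exp_dividing_surface <- function(defaults = list(
    cu = 4.2, kp_axis = seq(1, 60, by = 2), ki_axis = seq(20, 900, by = 60),
    td_hi = 0.5)) {
  p <- defaults
  dividing_surface(p$kp_axis, p$ki_axis, plant_params(p$cu), td_hi = p$td_hi)
}

exp_stability_slice <- function(defaults = list(
    cu = 4.2, td = 0.020, kp_axis = c(seq(0.5, 9.5, by = 1.5), 10,
                                      seq(12, 60, by = 2)))) {
  p <- defaults
  stability_slice(p$td, p$kp_axis, plant_params(p$cu))
}

exp_hybrid_bounds <- function(defaults = list(
    cu = 4.2, td = 0.020, kp_axis = seq(5, 55, by = 10),
    ki_axis = c(1, 150, 300, 500, 700, 900),
    sigma_list = c(0, 5, 30, 120, Inf), freq = 2, amp = 50,
    dt = 1e-4, duration = 5)) {
  p <- defaults
  hybrid_bound_map(p$kp_axis, p$ki_axis, plant_params(p$cu),
                   delay_model(td = p$td), p$sigma_list,
                   stimulus(p$amp, p$freq),
                   sim_config(dt = p$dt, duration = p$duration))
}

exp_continuous_error <- function(defaults = list(
    cu = 4.2, td = 0.020, kp_axis = seq(5, 55, by = 10),
    ki_axis = c(1, 150, 300, 500, 700, 900),
    freq_grid = seq(0.5, 3, by = 0.5), amp = 50, dt = 1e-4, duration = 5)) {
  p <- defaults
  grid <- expand.grid(kp_star = p$kp_axis, ki_star = p$ki_axis,
                      f_in = p$freq_grid, KEEP.OUT.ATTRS = FALSE)
  cfg <- sim_config(dt = p$dt, duration = p$duration)
  grid$sae <- mapply(function(kp, ki, f) {
    r <- simulate_hybrid(
      system_params(controller_gains(kp, ki), plant_params(p$cu),
                    delay_model(td = p$td), Inf),
      stimulus(p$amp, f), cfg)
    as.numeric(sae(r))
  }, grid$kp_star, grid$ki_star, grid$f_in)
  grid$td <- p$td
  grid
}

exp_sigma_map <- function(defaults = list(
    cu = 4.2, td = 0.020, kp_axis = seq(5, 55, by = 10),
    ki_axis = c(1, 150, 300, 500, 700),
    freq_grid = c(0.5, 3), sigma_grid = c(seq(0, 6, by = 0.5), Inf),
    amp = 50, dt = 1e-4, duration = 5)) {
  p <- defaults
  cfg <- sim_config(dt = p$dt, duration = p$duration)
  do.call(rbind, lapply(p$freq_grid, function(f) {
    m <- optimal_threshold_map(p$kp_axis, p$ki_axis, plant_params(p$cu),
                               delay_model(td = p$td), f, p$sigma_grid,
                               p$amp, cfg)
    out <- m$map
    out$f_in <- f
    out$continuous_fraction <- m$continuous_fraction
    out
  }))
}

exp_error_surface_at <- function(kp, ki, p) {
  error_surface(controller_gains(kp, ki), plant_params(p$cu),
                delay_model(td = p$td), p$sigma_grid, p$freq_grid, p$amp,
                sim_config(dt = p$dt, duration = p$duration))
}

exp_error_surface_fly <- function(defaults = list(
    cu = 4.2, td = 0.020, kp = 10, ki = 1,
    sigma_grid = c(seq(0, 6, by = 0.25), Inf),
    freq_grid = seq(0.5, 3, by = 0.5), amp = 50, dt = 1e-4, duration = 5)) {
  exp_error_surface_at(defaults$kp, defaults$ki, defaults)
}

exp_error_surface_mid <- function(defaults = list(
    cu = 4.2, td = 0.020, kp = 18, ki = 500,
    sigma_grid = c(seq(0, 6, by = 0.25), Inf),
    freq_grid = seq(0.5, 3, by = 0.5), amp = 50, dt = 1e-4, duration = 5)) {
  exp_error_surface_at(defaults$kp, defaults$ki, defaults)
}

exp_error_surface_high <- function(defaults = list(
    cu = 4.2, td = 0.020, kp = 60, ki = 700,
    sigma_grid = c(seq(0, 6, by = 0.25), Inf),
    freq_grid = seq(0.5, 3, by = 0.5), amp = 50, dt = 1e-4, duration = 5)) {
  exp_error_surface_at(defaults$kp, defaults$ki, defaults)
}

exp_margins <- function(defaults = list(
    cu = 4.2, td = 0.020,
    sets = list(c(10, 1), c(60, 700)))) {
  p <- defaults
  do.call(rbind, lapply(p$sets, function(s) {
    m <- gain_phase_margins(controller_gains(s[1], s[2]), plant_params(p$cu),
                            delay_model(td = p$td))
    data.frame(kp_star = s[1], ki_star = s[2], td = p$td,
               gain_margin_db = m$gain_margin_db,
               phase_margin_deg = m$phase_margin_deg,
               gain_crossover_hz = m$gain_crossover_hz,
               phase_crossover_hz = m$phase_crossover_hz)
  }))
}

exp_demo_traces <- function(defaults = list(
    cu = 4.2, td = 0.020, kp = 2, ki = 30,
    sigma_list = c(0.5, 1.5, 3.5, Inf), freq = 2, amp = 50,
    dt = 1e-4, duration = 3)) {
  p <- defaults
  cfg <- sim_config(dt = p$dt, duration = p$duration)
  do.call(rbind, lapply(p$sigma_list, function(sg) {
    r <- simulate_hybrid(
      system_params(controller_gains(p$kp, p$ki), plant_params(p$cu),
                    delay_model(td = p$td), sg),
      stimulus(p$amp, p$freq), cfg)
    d <- as.data.frame(r)
    d$sigma <- sg
    d
  }))
}

exp_adjusted_sigma_traces <- function(defaults = list(
    cu = 4.2, td = 0.020,
    sets = list(c(10, 1, 2.8), c(10, 500, 2.3)), freq = 3, amp = 50,
    dt = 1e-4, duration = 3)) {
  p <- defaults
  cfg <- sim_config(dt = p$dt, duration = p$duration)
  do.call(rbind, lapply(p$sets, function(s) {
    sim_one <- function(sg) {
      r <- simulate_hybrid(
        system_params(controller_gains(s[1], s[2]), plant_params(p$cu),
                      delay_model(td = p$td), sg),
        stimulus(p$amp, p$freq), cfg)
      d <- as.data.frame(r)
      d$kp_star <- s[1]
      d$ki_star <- s[2]
      d$sigma <- sg
      d$sae <- as.numeric(sae(r))
      d
    }
    rbind(sim_one(s[3]), sim_one(Inf))
  }))
}
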