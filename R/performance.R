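#' Sum-absolute error of a simulation
#'
#' The performance metric of the tracking loop:
#' \deqn{\epsilon_{SAE} = \sum_{t=0}^{t_f}
#'   |\dot\theta_{setpoint}(t) - \dot\theta_{out}(t)|}
#' a plain sum of absolute sample-wise differences over the full record,
#' transient included, with no normalization. SAE requires no linearity
#' assumption, so hybrid and continuous responses are compared in raw form;
#' values are comparable only at a fixed step and duration, which are
#' recorded as attributes `dt` and `t_f`. A diverged run has infinite SAE.
#'
#' @param result A `sim_result` from [simulate_hybrid()], or a numeric
#'   setpoint vector (then `output` must be given).
#' @param output Optional numeric output vector aligned with a numeric
#'   `result`.
#' @return Non-negative SAE (deg/s per sample, summed).
#' @examples
#' sae(c(1, -2, 3), c(0, 0, 0))   # 6
#' @export
sae <- function(result, output = NULL) {
  if (inherits(result, "sim_result")) {
    if (isTRUE(result$diverged))
      return(structure(Inf, dt = result$cfg$dt, t_f = result$cfg$duration))
    return(structure(sum(abs(result$setpoint - result$output)),
                     dt = result$cfg$dt, t_f = result$cfg$duration))
  }
  if (is.null(output)) stop("`output` required when `result` is a plain vector")
  if (length(result) != length(output))
    stop("setpoint and output lengths differ")
  sum(abs(result - output))
}

default_sigma_grid <- function() c(seq(0, 6, by = 0.1), Inf)

sae_for_sigma <- function(gains, plant, delay, sigma, stim, cfg) {
  r <- simulate_hybrid(system_params(gains, plant, delay, sigma), stim, cfg)
  list(sae = as.numeric(sae(r)), n_saccades = length(r$saccade_times),
       diverged = r$diverged)
}

#' Error surface over switching threshold and frequency
#'
#' Simulates one hybrid run per (sigma, frequency) cell for a fixed gain
#' pair and tabulates SAE, giving the error surface from which the optimal
#' switching threshold is read. The `Inf` entry of `sigma_grid` is the
#' continuous (no-saccade) system.
#'
#' @inheritParams is_stable
#' @param sigma_grid Switching thresholds in degrees, default 0 to 6 by 0.1
#'   plus `Inf`.
#' @param freq_grid Stimulus frequencies (Hz), default 0.5 to 3 by 0.5.
#' @param amplitude Stimulus amplitude (deg/s), default 50.
#' @param cfg A [sim_config()].
#' @return A data.frame with one row per cell: `kp_star`, `ki_star`, `td`,
#'   `sigma`, `f_in`, `sae`, `n_saccades`, `diverged`.
#' @export
error_surface <- function(gains, plant = plant_params(),
                          delay = delay_model(),
                          sigma_grid = default_sigma_grid(),
                          freq_grid = seq(0.5, 3, by = 0.5),
                          amplitude = 50, cfg = sim_config()) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  grid <- expand.grid(sigma = sigma_grid, f_in = freq_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- mapply(function(sg, f) {
    sae_for_sigma(gains, plant, delay, sg, stimulus(amplitude, f), cfg)
  }, grid$sigma, grid$f_in, SIMPLIFY = FALSE)
  data.frame(kp_star = gains$kp_star, ki_star = gains$ki_star,
             td = delay$td, sigma = grid$sigma, f_in = grid$f_in,
             sae = vapply(rows, `[[`, numeric(1), "sae"),
             n_saccades = vapply(rows, `[[`, numeric(1), "n_saccades"),
             diverged = vapply(rows, `[[`, logical(1), "diverged"))
}

#' Optimal switching threshold at one frequency
#'
#' Sweeps the switching threshold and returns the sigma minimizing SAE for
#' the given gain pair and stimulus frequency. When the continuous system
#' (the `Inf` sentinel) wins, or the best hybrid threshold improves on it by
#' less than `tie_tol` (relative), the continuous marker `Inf` is returned:
#' at that gain pair and frequency, saccades buy nothing.
#'
#' @inheritParams error_surface
#' @param f_in Stimulus frequency (Hz).
#' @param tie_tol Relative SAE improvement below which the continuous system
#'   is declared optimal (default 1e-3, i.e. 0.1%).
#' @return Optimal sigma in degrees, or `Inf` (continuous marker).
#' @examples
#' \donttest{
#' optimal_threshold(controller_gains(10, 1), f_in = 3)  # about 3 degrees
#' }
#' @export
optimal_threshold <- function(gains, plant = plant_params(),
                              delay = delay_model(), f_in = 1,
                              sigma_grid = default_sigma_grid(),
                              amplitude = 50, cfg = sim_config(),
                              tie_tol = 1e-3) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  stopifnot(!is.unsorted(sigma_grid))
  stim <- stimulus(amplitude, f_in)
  vals <- vapply(sigma_grid, function(sg) {
    sae_for_sigma(gains, plant, delay, sg, stim, cfg)$sae
  }, numeric(1))
  if (!any(is.finite(sigma_grid))) return(Inf)
  if (!is.infinite(sigma_grid[length(sigma_grid)])) {
    # no continuous sentinel supplied: plain argmin
    return(sigma_grid[which.min(vals)])
  }
  sae_cont <- vals[length(vals)]
  finite <- is.finite(sigma_grid)
  best <- which.min(vals[finite])
  sae_best <- vals[finite][best]
  if (!is.finite(sae_cont)) {
    # continuous system diverged: any finite-sigma optimum stands
    return(sigma_grid[finite][best])
  }
  if ((sae_cont - sae_best) / sae_cont <= tie_tol) Inf
  else sigma_grid[finite][best]
}

#' Optimal switching threshold across the gain space
#'
#' Maps [optimal_threshold()] over a gain grid at one stimulus frequency and
#' reports, alongside the per-pair optima, the fraction of the continuously
#' stable gain space where the continuous system is optimal (the
#' no-benefit-from-saccades region). That fraction shrinks as the stimulus
#' frequency rises.
#'
#' @inheritParams error_surface
#' @inheritParams optimal_threshold
#' @param kp_axis,ki_axis Gain grids.
#' @return An object of class `threshold_map`: list with `map` (data.frame:
#'   `kp_star`, `ki_star`, `stable`, `optimal_sigma`), `continuous_fraction`
#'   (share of stable pairs where `Inf` wins) and `f_in`.
#' @export
optimal_threshold_map <- function(kp_axis, ki_axis,
                                  plant = plant_params(),
                                  delay = delay_model(), f_in = 1,
                                  sigma_grid = default_sigma_grid(),
                                  amplitude = 50, cfg = sim_config(),
                                  tie_tol = 1e-3) {
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  grid <- expand.grid(kp_star = kp_axis, ki_star = ki_axis,
                      KEEP.OUT.ATTRS = FALSE)
  grid$stable <- mapply(function(kp, ki) {
    is_stable(controller_gains(kp, ki), plant, delay)
  }, grid$kp_star, grid$ki_star)
  grid$optimal_sigma <- mapply(function(kp, ki) {
    optimal_threshold(controller_gains(kp, ki), plant, delay, f_in,
                      sigma_grid, amplitude, cfg, tie_tol)
  }, grid$kp_star, grid$ki_star)
  frac <- mean(!is.finite(grid$optimal_sigma[grid$stable]))
  structure(list(map = grid, continuous_fraction = frac, f_in = f_in),
            class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat("<threshold_map> f_in =", x$f_in, "Hz;",
      nrow(x$map), "gain pairs;",
      sprintf("continuous system optimal on %.1f%% of the stable space\n",
              100 * x$continuous_fraction))
  invisible(x)
}

#' Hybrid response-bound map over the gain space
#'
#' Evaluates the peak-to-peak response bound \eqn{S_H} of the hybrid system
#' at each (gain pair, sigma) combination for one stimulus. With a small
#' threshold the bound is small and nearly uniform everywhere, including at
#' continuously unstable gain pairs; as sigma grows the bound approaches
#' the continuous behavior, which is finite only inside the stable region.
#' The continuous stability of each pair is included for overlay against
#' the [stability_slice()] boundary.
#'
#' @inheritParams optimal_threshold_map
#' @param sigma_list Switching thresholds to evaluate (degrees; may include
#'   `Inf`).
#' @param stim A [stimulus()], default 2 Hz at 50 deg/s.
#' @return A data.frame: `kp_star`, `ki_star`, `sigma`, `s_h` (deg/s),
#'   `stable`, `diverged`.
#' @export
hybrid_bound_map <- function(kp_axis, ki_axis,
                             plant = plant_params(),
                             delay = delay_model(),
                             sigma_list = c(0, 5, 30, 120, Inf),
                             stim = stimulus(50, 2),
                             cfg = sim_config()) {
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  grid <- expand.grid(kp_star = kp_axis, ki_star = ki_axis,
                      sigma = sigma_list, KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(kp, ki, sg) {
    r <- simulate_hybrid(system_params(controller_gains(kp, ki), plant,
                                       delay, sg), stim, cfg)
    c(response_bound(r), as.numeric(r$diverged))
  }, grid$kp_star, grid$ki_star, grid$sigma)
  grid$s_h <- res[1, ]
  grid$diverged <- res[2, ] > 0
  stable_lut <- mapply(function(kp, ki) {
    is_stable(controller_gains(kp, ki), plant, delay)
  }, grid$kp_star, grid$ki_star)
  grid$stable <- stable_lut
  grid
}
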