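#' Yaw plant parameters
#'
#' The plant is the first-order yaw dynamics of the fly body,
#' \eqn{1/(I s + C_u)} from torque to angular velocity. All analyses use the
#' normalized damping-to-inertia ratio \eqn{C_u^* = C_u / I} (units 1/s);
#' absolute inertia and damping are accepted at the boundary and converted.
#' The default \eqn{C_u^* = 4.2} is the experimentally derived ratio for
#' \emph{D. melanogaster}.
#'
#' @param cu_star Damping-to-inertia ratio (1/s). Ignored when both `inertia`
#'   and `damping` are given.
#' @param inertia Yaw inertia \eqn{I} (N m s^2), optional.
#' @param damping Yaw damping \eqn{C_u} (N m s), optional.
#' @return An object of class `plant_params` with fields `inertia`, `damping`
#'   (possibly `NA` when only the ratio is known) and `cu_star`.
#' @examples
#' plant_params()                       # fly default, cu_star = 4.2
#' plant_params(inertia = 5e-13, damping = 2.1e-12)
#' @export
plant_params <- function(cu_star = 4.2, inertia = NULL, damping = NULL) {
  if (!is.null(inertia) || !is.null(damping)) {
    if (is.null(inertia) || is.null(damping))
      stop("supply both `inertia` and `damping`, or neither")
    stopifnot(is.numeric(inertia), length(inertia) == 1L, is.finite(inertia),
              is.numeric(damping), length(damping) == 1L, is.finite(damping))
    if (inertia <= 0) stop("`inertia` must be > 0")
    if (damping <= 0) stop("`damping` must be > 0")
    cu_star <- damping / inertia
  } else {
    stopifnot(is.numeric(cu_star), length(cu_star) == 1L, is.finite(cu_star))
    if (cu_star <= 0) stop("`cu_star` must be > 0")
    inertia <- NA_real_
    damping <- NA_real_
  }
  structure(list(inertia = inertia, damping = damping, cu_star = cu_star),
            class = "plant_params")
}

#' PI controller gains
#'
#' Gains of the smooth (optomotor) PI controller in normalized form:
#' \eqn{K_P^*} (1/s) and \eqn{K_I^*} (1/s^2) are the absolute gains divided by
#' the yaw inertia. Absolute gains may be supplied together with `inertia`.
#' The experimentally determined pair for the fly is
#' \eqn{(K_P^*, K_I^*) = (10, 1)}.
#'
#' @param kp_star Normalized proportional gain (1/s), >= 0.
#' @param ki_star Normalized integral gain (1/s^2), >= 0.
#' @param kp,ki Absolute gains (N m s, N m); require `inertia`.
#' @param inertia Yaw inertia used to normalize absolute gains.
#' @return An object of class `controller_gains`.
#' @examples
#' controller_gains(10, 1)    # fly-like gain pair
#' controller_gains(kp = 5e-12, ki = 5e-13, inertia = 5e-13)
#' @export
controller_gains <- function(kp_star = NULL, ki_star = NULL,
                             kp = NULL, ki = NULL, inertia = NULL) {
  if (!is.null(kp) || !is.null(ki)) {
    if (is.null(kp) || is.null(ki) || is.null(inertia))
      stop("absolute gains require `kp`, `ki` and `inertia`")
    if (inertia <= 0) stop("`inertia` must be > 0")
    kp_star <- kp / inertia
    ki_star <- ki / inertia
  }
  stopifnot(is.numeric(kp_star), length(kp_star) == 1L, is.finite(kp_star),
            is.numeric(ki_star), length(ki_star) == 1L, is.finite(ki_star))
  if (kp_star < 0) stop("`kp_star` must be >= 0")
  if (ki_star < 0) stop("`ki_star` must be >= 0")
  structure(list(kp_star = kp_star, ki_star = ki_star),
            class = "controller_gains")
}

#' Transport delay model
#'
#' Sensorimotor transport delay between the visual error and the motor
#' torque. The default 20 ms is the fly's visuomotor transport latency. For
#' pole-based analysis the pure delay \eqn{e^{-s t_d}} is replaced by an
#' `[n/n]` Pade rational approximant of order `pade_order` (default 5).
#'
#' @param td Transport delay in seconds, >= 0.
#' @param pade_order Order of the Pade approximant (integer >= 1).
#' @return An object of class `delay_model`.
#' @export
delay_model <- function(td = 0.020, pade_order = 5) {
  stopifnot(is.numeric(td), length(td) == 1L, is.finite(td))
  if (td < 0) stop("`td` must be >= 0")
  pade_order <- as.integer(pade_order)
  if (is.na(pade_order) || pade_order < 1L) stop("`pade_order` must be >= 1")
  structure(list(td = td, pade_order = pade_order), class = "delay_model")
}

#' Full hybrid-system parameter set
#'
#' Bundles the controller gains, plant, delay and the saccadic switching
#' threshold sigma into one point of the explored parameter space. `sigma` is
#' the integrated-error magnitude (degrees) at which a saccade fires;
#' `sigma = Inf` disables the saccadic system entirely and leaves the purely
#' continuous PI loop, `sigma = 0` fires a saccade at every step.
#'
#' @param gains A [controller_gains()] object.
#' @param plant A [plant_params()] object.
#' @param delay A [delay_model()] object.
#' @param sigma Switching threshold in degrees (>= 0) or `Inf`.
#' @return An object of class `system_params`.
#' @export
system_params <- function(gains, plant = plant_params(),
                          delay = delay_model(), sigma = Inf) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, !is.na(sigma))
  if (sigma < 0) stop("`sigma` must be >= 0 (or Inf for the continuous system)")
  structure(list(gains = gains, plant = plant, delay = delay, sigma = sigma),
            class = "system_params")
}

#' Sinusoidal stimulus specification
#'
#' Angular-velocity setpoint \eqn{A \sin(2\pi f t + \phi)} in deg/s, the
#' wide-field visual rotation the stabilization reflex must track.
#'
#' @param amplitude Peak angular velocity (deg/s), >= 0.
#' @param frequency Stimulus frequency (Hz), > 0.
#' @param phase Phase offset (radians).
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(amplitude = 50, frequency = 1, phase = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.finite(amplitude),
            is.numeric(frequency), length(frequency) == 1L,
            is.finite(frequency),
            is.numeric(phase), length(phase) == 1L, is.finite(phase))
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (frequency <= 0) stop("`frequency` must be > 0")
  structure(list(kind = "sinusoid", amplitude = amplitude,
                 frequency = frequency, phase = phase),
            class = "stimulus")
}

#' Simulation configuration
#'
#' Fixed-step integration settings for [simulate_hybrid()]. The transport
#' delay is realized as a ring buffer of `round(td / dt)` samples; `td` is
#' rounded to an integer multiple of `dt` with a warning when needed.
#'
#' @param dt Integration step (s), default 1e-4.
#' @param duration Total simulated time (s), default 5.
#' @param record_states Keep full state traces in the result (default TRUE).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-4, duration = 5, record_states = TRUE) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt),
            is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (dt <= 0) stop("`dt` must be > 0")
  if (duration <= 0) stop("`duration` must be > 0")
  structure(list(dt = dt, duration = duration,
                 record_states = isTRUE(record_states)),
            class = "sim_config")
}

# Coercion helpers: numeric shorthands accepted at every module boundary.
as_gains <- function(x) {
  if (inherits(x, "controller_gains")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(controller_gains(x[[1]], x[[2]]))
  stop("expected a `controller_gains` object or a numeric (kp_star, ki_star) pair")
}

as_plant <- function(x) {
  if (inherits(x, "plant_params")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(plant_params(cu_star = x))
  stop("expected a `plant_params` object or a scalar cu_star")
}

as_delay <- function(x) {
  if (inherits(x, "delay_model")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(delay_model(td = x))
  stop("expected a `delay_model` object or a scalar delay in seconds")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params> first-order yaw plant, Cu* =", x$cu_star, "1/s\n")
  invisible(x)
}

#' @export
print.controller_gains <- function(x, ...) {
  cat("<controller_gains> KP* =", x$kp_star, "1/s, KI* =", x$ki_star, "1/s^2\n")
  invisible(x)
}

#' @export
print.delay_model <- function(x, ...) {
  cat("<delay_model> td =", x$td * 1000, "ms, Pade order", x$pade_order, "\n")
  invisible(x)
}

#' @export
print.system_params <- function(x, ...) {
  cat("<system_params> KP* =", x$gains$kp_star, ", KI* =", x$gains$ki_star,
      ", Cu* =", x$plant$cu_star, ", td =", x$delay$td * 1000, "ms, sigma =",
      if (is.finite(x$sigma)) paste0(x$sigma, " deg") else "Inf (continuous)",
      "\n")
  invisible(x)
}
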