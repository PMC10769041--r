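#' Sample a stimulus on the simulation time grid
#'
#' Returns the setpoint angular velocity
#' \eqn{\dot\theta_{setpoint}(t) = A \sin(2\pi f t + \phi)} sampled at the
#' configuration's fixed step, including both endpoints `t = 0` and
#' `t = duration`.
#'
#' @param stim A [stimulus()].
#' @param cfg A [sim_config()].
#' @return Numeric vector of setpoint samples (deg/s) with attribute `time`.
#' @examples
#' sp <- make_stimulus(stimulus(50, 2), sim_config(dt = 1e-3, duration = 1))
#' @export
make_stimulus <- function(stim, cfg = sim_config()) {
  stopifnot(inherits(stim, "stimulus"), inherits(cfg, "sim_config"))
  tt <- seq(0, cfg$duration, by = cfg$dt)
  sp <- stim$amplitude * sin(2 * pi * stim$frequency * tt + stim$phase)
  attr(sp, "time") <- tt
  sp
}

#' Simulate the hybrid smooth-saccadic system
#'
#' Fixed-step (RK4) time-domain integration of the switched loop. The error
#' \eqn{e(t) = \dot\theta_{setpoint} - \dot\theta_{out}} passes through a
#' transport-delay line; the delayed error drives both the PI control torque
#' \eqn{K_P^* e_d + K_I^* \int e_d\,dt} and the saccade trigger
#' \eqn{|\int e_d\,dt| \ge \sigma}. The plant is the first-order lag
#' \eqn{d\dot\theta_{out}/dt = u - C_u^* \dot\theta_{out}}. When the trigger
#' fires, the jump map resets the integrator and the plant state to zero and
#' (by default) flushes the delay line, re-basing the system; flow then
#' resumes. `sigma = Inf` disables the jump map, leaving the purely
#' continuous linear loop; `sigma = 0` fires at every step.
#'
#' The delay is a ring buffer of `round(td/dt)` samples; `td` not an integer
#' multiple of `dt` is rounded with a warning. All initial conditions are
#' zero. A non-finite or exploding state (possible only with `sigma = Inf`
#' and continuously unstable gains) halts the run, which is returned partial
#' and flagged `diverged`.
#'
#' @param params A [system_params()] (gains, plant, delay, sigma).
#' @param stim A [stimulus()].
#' @param cfg A [sim_config()].
#' @param flush_delay Flush the delay-line contents on each saccade
#'   (default TRUE); set FALSE to preserve in-transit error for sensitivity
#'   analysis.
#' @param diverge_limit State magnitude treated as divergence (default 1e9).
#' @return An object of class `sim_result`: list with `time` (s), `setpoint`
#'   and `output` (deg/s), `integrator_state` (deg), `saccade_times` (s),
#'   `diverged` flag, and the input `params`/`cfg` as metadata.
#' @examples
#' r <- simulate_hybrid(
#'   system_params(controller_gains(10, 1), sigma = 3),
#'   stimulus(50, 2), sim_config(duration = 2))
#' length(r$saccade_times)
#' @export
simulate_hybrid <- function(params, stim, cfg = sim_config(),
                            flush_delay = TRUE, diverge_limit = 1e9) {
  stopifnot(inherits(params, "system_params"), inherits(stim, "stimulus"),
            inherits(cfg, "sim_config"))
  td <- params$delay$td
  nd <- as.integer(round(td / cfg$dt))
  if (abs(nd * cfg$dt - td) > 1e-9 * max(td, cfg$dt)) {
    warning(sprintf(
      "delay %.6g s is not an integer multiple of dt = %.6g s; rounded to %.6g s",
      td, cfg$dt, nd * cfg$dt))
  }
  sp <- make_stimulus(stim, cfg)
  tt <- attr(sp, "time")
  raw <- sim_hybrid_cpp(params$gains$kp_star, params$gains$ki_star,
                        params$plant$cu_star, nd, params$sigma,
                        as.numeric(sp), cfg$dt, isTRUE(flush_delay),
                        diverge_limit)
  res <- list(time = tt, setpoint = as.numeric(sp), output = raw$output,
              integrator_state = raw$integrator,
              saccade_times = raw$saccade_times,
              diverged = raw$diverged, n_valid = raw$last_index,
              params = params, cfg = cfg)
  if (!cfg$record_states) res$integrator_state <- NULL
  structure(res, class = "sim_result")
}

#' Peak-to-peak response bound of a simulation
#'
#' The hybrid system's stability surrogate: the absolute bounding
#' \eqn{S_H = \max(\dot\theta_{out}) - \min(\dot\theta_{out})} of the output
#' angular velocity over the full record. Any finite switching threshold
#' bounds the response at a finite level even for continuously unstable
#' gains; a diverged run (only possible with `sigma = Inf`) returns `Inf`.
#'
#' @param result A `sim_result` from [simulate_hybrid()].
#' @return Response bound in deg/s (`Inf` if the run diverged).
#' @export
response_bound <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (isTRUE(result$diverged)) return(Inf)
  out <- result$output
  max(out) - min(out)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$time), "samples over", max(x$time), "s;",
      length(x$saccade_times), "saccades",
      if (isTRUE(x$diverged)) "[DIVERGED]" else "", "\n")
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  graphics::plot(x$time, x$setpoint, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "angular velocity (deg/s)", ...)
  graphics::lines(x$time, x$output, col = "firebrick")
  if (length(x$saccade_times))
    graphics::abline(v = x$saccade_times, col = "steelblue", lty = 3)
  invisible(x)
}

#' Convert a simulation result to a data.frame
#'
#' One row per sample: time, setpoint, output, integrator state and a
#' saccade flag marking the samples at which a reset occurred.
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @export
as.data.frame.sim_result <- function(x, ...) {
  d <- data.frame(time = x$time, setpoint = x$setpoint, output = x$output)
  if (!is.null(x$integrator_state)) d$integrator <- x$integrator_state
  d$saccade <- d$time %in% x$saccade_times
  d
}
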