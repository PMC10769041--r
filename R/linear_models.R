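#' Open-loop transfer function of the continuous system
#'
#' Builds the loop gain of the smooth (PI) velocity-control loop,
#' \deqn{G(s) = D(s)\,\frac{K_P^* s + K_I^*}{s^2 + C_u^* s}}
#' where \eqn{D(s)} is the delay term: the Pade approximant by default, or
#' the unit transfer function (`delay_form = "none"`) when the caller intends
#' to multiply by the exact \eqn{e^{-j\omega t_d}} on the imaginary axis, as
#' [nyquist_curve()] does.
#'
#' @param gains A [controller_gains()] (or numeric pair).
#' @param plant A [plant_params()] (or scalar cu_star).
#' @param delay A [delay_model()] (or scalar seconds).
#' @param delay_form `"pade"` (default) or `"none"`.
#' @return A [rational_tf()].
#' @examples
#' open_loop_tf(controller_gains(10, 1), delay_form = "none")
#' @export
open_loop_tf <- function(gains, plant = plant_params(),
                         delay = delay_model(),
                         delay_form = c("pade", "none")) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  delay_form <- match.arg(delay_form)
  num <- c(gains$kp_star, gains$ki_star)
  den <- c(1, plant$cu_star, 0)
  if (delay_form == "pade" && delay$td > 0) {
    P <- pade_tf(delay)
    num <- pracma::polymul(P$num, num)
    den <- pracma::polymul(P$den, den)
  }
  rational_tf(num, den)
}

#' Closed-loop transfer function of the continuous system
#'
#' Forms the closed-loop velocity-tracking transfer function
#' \deqn{H(s) = \frac{P^n(t_d, s)(K_P^* s + K_I^*)}
#'                   {s^2 + C_u^* s + P^n(t_d, s)(K_P^* s + K_I^*)}}
#' with the Pade numerator/denominator multiplied through so that both `num`
#' and `den` are polynomials. Whenever \eqn{K_I^* > 0} the DC gain is
#' \eqn{H(0) = 1}: the integrator enforces perfect steady-state velocity
#' tracking. For `td = 0` this reduces to the delay-free closed loop with
#' denominator \eqn{s^2 + (C_u^* + K_P^*) s + K_I^*}, which is stable for all
#' positive gains.
#'
#' @inheritParams open_loop_tf
#' @return A [rational_tf()].
#' @examples
#' H <- closed_loop_tf(controller_gains(10, 1))
#' Mod(tf_eval(H, 0i))   # DC gain 1
#' @export
closed_loop_tf <- function(gains, plant = plant_params(),
                           delay = delay_model()) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  P <- pade_tf(delay)
  fwd_num <- pracma::polymul(P$num, c(gains$kp_star, gains$ki_star))
  plant_den <- c(1, plant$cu_star, 0)
  den <- poly_add(pracma::polymul(plant_den, P$den), fwd_num)
  rational_tf(fwd_num, den)
}
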