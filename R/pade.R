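#' Pade approximant of a pure transport delay
#'
#' Returns the diagonal `[n/n]` Pade rational approximation of the delay
#' \eqn{e^{-s t_d}}, the standard device for bringing a transport delay into
#' pole-based linear analysis. The approximant is all-pass
#' (\eqn{|P(j\omega)| = 1}) and matches the delay phase \eqn{-\omega t_d}
#' closely for \eqn{\omega t_d} well below the order.
#'
#' The coefficients of the `[n/n]` approximant of \eqn{e^{-x}} are
#' \deqn{P(x) = \frac{\sum_{k=0}^n c_k (-x)^k}{\sum_{k=0}^n c_k x^k}, \quad
#'       c_k = \frac{(2n-k)!\, n!}{(2n)!\, k!\, (n-k)!}}
#' with \eqn{x = s t_d}.
#'
#' @param delay A [delay_model()] (or scalar delay in seconds, order 5).
#' @return A [rational_tf()] with numerator and denominator of degree
#'   `pade_order`; the unit transfer function when `td = 0`.
#' @examples
#' pade_tf(delay_model(td = 0.020, pade_order = 5))
#' pade_tf(0)   # no delay: unit transfer function
#' @export
pade_tf <- function(delay = delay_model()) {
  delay <- as_delay(delay)
  td <- delay$td
  n <- delay$pade_order
  if (td == 0) return(rational_tf(1, 1))
  k <- 0:n
  ck <- exp(lfactorial(2 * n - k) + lfactorial(n) -
              lfactorial(2 * n) - lfactorial(k) - lfactorial(n - k))
  # coefficient of s^k is ck * (+-td)^k; store descending
  rational_tf(rev(ck * (-td)^k), rev(ck * td^k))
}
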