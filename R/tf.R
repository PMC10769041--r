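#' Rational transfer function
#'
#' Lightweight container for a single-input single-output rational transfer
#' function \eqn{N(s)/D(s)} with real polynomial coefficients stored in
#' descending powers of s. This is the currency of all the linear analyses:
#' the open loop \eqn{G(s)}, the closed loop \eqn{H(s)} and the Pade delay
#' approximant are all `rational_tf` objects.
#'
#' Exactly-zero leading coefficients are trimmed so the denominator degree is
#' well defined; nonzero coefficients are kept regardless of magnitude, since
#' the Pade polynomials legitimately span many orders of magnitude
#' (coefficients scale with powers of the delay).
#'
#' @param num,den Numeric coefficient vectors, descending powers of s.
#' @return An object of class `rational_tf`.
#' @examples
#' rational_tf(c(10, 1), c(1, 4.2, 0))   # (10 s + 1) / (s^2 + 4.2 s)
#' @export
rational_tf <- function(num, den) {
  stopifnot(is.numeric(num), length(num) >= 1L, all(is.finite(num)),
            is.numeric(den), length(den) >= 1L, all(is.finite(den)))
  num <- trim_poly(num)
  den <- trim_poly(den)
  if (all(den == 0)) stop("denominator is identically zero")
  structure(list(num = num, den = den), class = "rational_tf")
}

# drop exactly-zero leading coefficients; degree-reducing near-cancellation
# never occurs in the loop assemblies (all leading terms are positive), and
# a magnitude threshold would truncate the genuinely tiny td^n-scale leading
# coefficients of the Pade polynomials
trim_poly <- function(p) {
  keep <- which(p != 0)
  if (length(keep) == 0L) return(0)
  p[keep[1]:length(p)]
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(rep(0, n - length(a)), a) + c(rep(0, n - length(b)), b)
}

#' Evaluate a transfer function
#'
#' Horner evaluation of \eqn{N(s)/D(s)} at (possibly complex) points `s`.
#'
#' @param tf A [rational_tf()].
#' @param s Numeric or complex vector of evaluation points.
#' @return Complex vector of the same length as `s`.
#' @export
tf_eval <- function(tf, s) {
  stopifnot(inherits(tf, "rational_tf"))
  polyval_c(tf$num, s) / polyval_c(tf$den, s)
}

polyval_c <- function(p, s) {
  r <- rep(0 + 0i, length(s))
  for (coef in p) r <- r * s + coef
  r
}

#' Frequency response of a transfer function
#'
#' @param tf A [rational_tf()].
#' @param omega Angular frequencies (rad/s).
#' @return Complex vector `tf(j omega)`.
#' @export
tf_freqresp <- function(tf, omega) tf_eval(tf, 1i * omega)

#' Poles of a transfer function
#'
#' Roots of the denominator polynomial via [polyroot()].
#'
#' @param tf A [rational_tf()].
#' @return Complex vector of poles (empty when the denominator is constant).
#' @export
tf_poles <- function(tf) {
  stopifnot(inherits(tf, "rational_tf"))
  den <- tf$den
  if (length(den) == 1L) return(complex(0))
  polyroot(rev(den))
}

#' @export
print.rational_tf <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = " ")
  cat("<rational_tf> degree", length(x$num) - 1L, "/", length(x$den) - 1L, "\n")
  cat("  num:", fmt(x$num), "\n  den:", fmt(x$den), "\n")
  invisible(x)
}
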