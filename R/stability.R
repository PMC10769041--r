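#' Pole-based stability of the continuous system
#'
#' The continuous (saccade-free) loop is declared stable when every pole of
#' the Pade-approximated closed-loop transfer function lies strictly in the
#' left half plane, with real part below `-tol`. Marginal poles (real part
#' within the tolerance band of zero) are conservatively classified unstable.
#'
#' @inheritParams open_loop_tf
#' @param tol Stability margin on the pole real parts (default 1e-9).
#' @return Logical scalar.
#' @examples
#' is_stable(controller_gains(10, 1))                  # fly pair at 20 ms: stable
#' is_stable(controller_gains(10, 900))                # far above the boundary
#' @export
is_stable <- function(gains, plant = plant_params(), delay = delay_model(),
                      tol = 1e-9) {
  H <- closed_loop_tf(gains, plant, delay)
  if (length(H$den) < 2L) stop("degenerate closed-loop denominator")
  all(Re(tf_poles(H)) < -tol)
}

#' Maximum stable delay for a gain pair
#'
#' Bisects the transport delay for the stability transition of [is_stable()].
#' The delay-free system is stable for any positive gains, so the transition
#' is bracketed by `[0, td_hi]`; when the system is stable throughout the
#' bracket, `td_hi` is returned with attribute `censored = TRUE`.
#'
#' @inheritParams is_stable
#' @param td_hi Upper end of the search bracket (s), default 0.5.
#' @param tol_td Bisection tolerance on the delay (s), default 1e-5.
#' @return Maximum stable delay in seconds (attribute `censored` when the
#'   bracket never went unstable).
#' @examples
#' max_stable_delay(controller_gains(10, 1))   # well above the fly's 20 ms
#' @export
max_stable_delay <- function(gains, plant = plant_params(), td_hi = 0.5,
                             tol_td = 1e-5) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  if (is_stable(gains, plant, delay_model(td = td_hi))) {
    return(structure(td_hi, censored = TRUE))
  }
  lo <- 0
  hi <- td_hi
  while (hi - lo > tol_td) {
    mid <- (lo + hi) / 2
    if (is_stable(gains, plant, delay_model(td = mid))) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, censored = FALSE)
}

#' Boolean stability field over the gain-delay space
#'
#' Evaluates [is_stable()] on the full tensor grid of proportional gain,
#' integral gain and delay, producing the binary stability point cloud of
#' the continuous system.
#'
#' @param kp_axis,ki_axis Gain grids (1/s, 1/s^2).
#' @param td_axis Delay grid (s).
#' @inheritParams is_stable
#' @return A data.frame with columns `kp_star`, `ki_star`, `td`, `stable`.
#' @export
stability_field <- function(kp_axis = seq(0.5, 60, length.out = 40),
                            ki_axis = seq(0.5, 900, length.out = 40),
                            td_axis = seq(0.001, 0.1, length.out = 25),
                            plant = plant_params()) {
  grid <- expand.grid(kp_star = kp_axis, ki_star = ki_axis, td = td_axis,
                      KEEP.OUT.ATTRS = FALSE)
  grid$stable <- mapply(function(kp, ki, td) {
    is_stable(controller_gains(kp, ki), plant, delay_model(td = td))
  }, grid$kp_star, grid$ki_star, grid$td)
  grid
}

#' Dividing surface: maximum stable delay per gain pair
#'
#' The surface separating the stable and unstable regions of the
#' gain-delay space: for each gain pair, the largest delay at which the
#' continuous system remains stable, found by [max_stable_delay()] bisection.
#' The surface is strictly above zero everywhere because the delay-free
#' system is universally stable.
#'
#' @inheritParams stability_field
#' @inheritParams max_stable_delay
#' @return A data.frame with columns `kp_star`, `ki_star`,
#'   `max_stable_delay` (s), `censored`.
#' @export
dividing_surface <- function(kp_axis = seq(0.5, 60, length.out = 40),
                             ki_axis = seq(0.5, 900, length.out = 40),
                             plant = plant_params(), td_hi = 0.5,
                             tol_td = 1e-5) {
  grid <- expand.grid(kp_star = kp_axis, ki_star = ki_axis,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(kp, ki) {
    msd <- max_stable_delay(controller_gains(kp, ki), plant, td_hi, tol_td)
    c(msd, as.numeric(isTRUE(attr(msd, "censored"))))
  }, grid$kp_star, grid$ki_star)
  grid$max_stable_delay <- res[1, ]
  grid$censored <- res[2, ] > 0
  grid
}

#' Stability boundary in the gain plane at fixed delay
#'
#' For each proportional gain on `kp_axis`, bisects for the largest integral
#' gain at which the system is still stable at delay `td`. The region under
#' the returned curve is the stable gain region; at the fly's 20 ms delay
#' the boundary is approximately parabolic. Gain pairs stable all the way up
#' to `ki_hi` get the sentinel `Inf` (as happens for `td` near zero).
#'
#' @param td Delay (s), > 0.
#' @inheritParams stability_field
#' @param ki_hi Upper end of the integral-gain bracket, default 2000.
#' @param tol_ki Bisection tolerance on ki, default 1e-3.
#' @return A data.frame with columns `kp_star`, `ki_max`.
#' @export
stability_slice <- function(td = 0.020,
                            kp_axis = seq(0.5, 60, length.out = 40),
                            plant = plant_params(), ki_hi = 2000,
                            tol_ki = 1e-3) {
  stopifnot(td > 0)
  delay <- delay_model(td = td)
  ki_max <- vapply(kp_axis, function(kp) {
    if (is_stable(controller_gains(kp, ki_hi), plant, delay)) return(Inf)
    lo <- 0
    hi <- ki_hi
    while (hi - lo > tol_ki) {
      mid <- (lo + hi) / 2
      if (is_stable(controller_gains(kp, mid), plant, delay)) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(kp_star = kp_axis, ki_max = ki_max)
}

#' Nyquist curve of the loop gain with exact delay
#'
#' Evaluates the open-loop frequency response
#' \eqn{G(j\omega) = e^{-j\omega t_d} (K_P^* j\omega + K_I^*) /
#' ((j\omega)^2 + C_u^* j\omega)} on a strictly positive ascending frequency
#' grid. The pure delay is exactly evaluable on the imaginary axis, so no
#' Pade approximation enters here; this is the cross-check route against the
#' pole-based stability pipeline. The open loop has a pole at the origin, so
#' \eqn{\omega = 0} is not admissible and is signalled as an error rather
#' than dropped.
#'
#' @inheritParams is_stable
#' @param omega Ascending vector of strictly positive frequencies (rad/s).
#' @return An object of class `nyquist_curve`: list with `omega` and the
#'   complex `response`.
#' @export
nyquist_curve <- function(gains, plant = plant_params(),
                          delay = delay_model(),
                          omega = pracma::logseq(1e-2, 1e3, 2000)) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  if (any(omega <= 0))
    stop("`omega` must be strictly positive: the open loop has a pole at the origin")
  if (is.unsorted(omega)) stop("`omega` must be ascending")
  jw <- 1i * omega
  resp <- exp(-jw * delay$td) *
    (gains$kp_star * jw + gains$ki_star) / (jw^2 + plant$cu_star * jw)
  structure(list(omega = omega, response = resp, gains = gains,
                 plant = plant, delay = delay),
            class = "nyquist_curve")
}

#' Nyquist encirclements of -1 with the exact delay
#'
#' Counts the winding number of the exact-delay Nyquist contour about the
#' critical point -1. The contour is the classical D-contour: both halves of
#' the imaginary axis with a small right-half-plane indentation around the
#' open-loop pole at the origin; the arc at infinity maps to the origin
#' (the plant rolls off) and contributes nothing. The open loop has no
#' right-half-plane poles, so the closed loop is stable iff the winding
#' number is zero. Used as an independent cross-check of [is_stable()];
#' disagreements are Pade artifacts.
#'
#' @inheritParams is_stable
#' @param n_grid Samples per imaginary-axis branch.
#' @return Integer winding number (0 = stable).
#' @export
nyquist_encirclements <- function(gains, plant = plant_params(),
                                  delay = delay_model(), n_grid = 40000) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  kp <- gains$kp_star
  ki <- gains$ki_star
  cu <- plant$cu_star
  td <- delay$td
  L <- function(s) exp(-s * td) * (kp * s + ki) / (s^2 + cu * s)
  # indentation radius: small enough that |L| >> 1 on the arc
  eps <- max(ki, 1e-3) / (cu * 1e4)
  omega_max <- max(1e3, 2e3 * (kp + 1))
  w <- pracma::logseq(eps, omega_max, n_grid)
  theta <- seq(-pi / 2, pi / 2, length.out = 2000)
  s_path <- c(1i * rev(-w),          # jw from -omega_max up to -eps
              eps * exp(1i * theta), # RHP indentation around the origin
              1i * w)                # jw from eps to omega_max
  z <- L(s_path) + 1                 # vector from -1 to the curve
  z <- c(z, z[1])                    # close (arc at infinity ~ origin)
  dphi <- Arg(z[-1] / z[-length(z)])
  as.integer(round(sum(dphi) / (2 * pi)))
}

#' Gain and phase margins of the continuous loop
#'
#' Classical stability margins of the Pade-approximated loop gain, matching
#' the pole-based pipeline used everywhere else in the linear analysis. The
#' gain margin is \eqn{-20 \log_{10} |G|} at the phase crossover (loop phase
#' equal to -180 deg modulo 360); the phase margin is 180 deg plus the loop
#' phase at the unity-gain crossover. When several crossovers exist the
#' smallest margin is reported. A missing crossover yields the `Inf`
#' sentinel and an `NA` crossover frequency.
#'
#' Crossovers are located on a dense logarithmic frequency grid with
#' unwrapped phase and refined by root bracketing, giving crossover
#' frequencies accurate to well below 0.1%.
#'
#' @inheritParams is_stable
#' @param omega_range Frequency search range (rad/s), default `c(1e-3, 1e4)`.
#' @param n_grid Size of the search grid.
#' @return An object of class `margins`: list with `gain_margin_db`,
#'   `phase_margin_deg`, `gain_crossover_hz` (unity-gain crossover),
#'   `phase_crossover_hz` (-180 deg crossover).
#' @examples
#' gain_phase_margins(controller_gains(10, 1))
#' @export
gain_phase_margins <- function(gains, plant = plant_params(),
                               delay = delay_model(),
                               omega_range = c(1e-3, 1e4), n_grid = 20000) {
  gains <- as_gains(gains)
  plant <- as_plant(plant)
  delay <- as_delay(delay)
  G <- open_loop_tf(gains, plant, delay)
  w <- pracma::logseq(omega_range[1], omega_range[2], n_grid)
  resp <- tf_freqresp(G, w)
  mag <- Mod(resp)
  ph <- signal::unwrap(Arg(resp)) * 180 / pi

  refine_w <- function(f, lo, hi) {
    uniroot(f, c(lo, hi), tol = min(lo, hi) * 1e-8)$root
  }

  # phase crossovers: unwrapped phase through -180 - 360k, k >= 0
  gm_db <- Inf
  wpc <- NA_real_
  kmax <- floor((-min(ph) - 180) / 360)
  if (kmax >= 0) {
    for (k in 0:kmax) {
      target <- -180 - 360 * k
      idx <- which(diff(sign(ph - target)) != 0)
      for (i in idx) {
        # Arg(-G) is continuous (= 0) at this crossover: robust local root
        f <- function(x) {
          a <- Arg(-tf_freqresp(G, x)) * 180 / pi
          a - (a > 90) * 360 + (a < -90) * 360  # keep branch near 0
        }
        wr <- tryCatch(refine_w(f, w[i], w[i + 1]), error = function(e) NA)
        if (is.na(wr)) next
        g_here <- -20 * log10(Mod(tf_freqresp(G, wr)))
        if (g_here < gm_db) {
          gm_db <- g_here
          wpc <- wr
        }
      }
    }
  }

  # unity-gain crossovers
  pm_deg <- Inf
  wgc <- NA_real_
  idx <- which(diff(sign(mag - 1)) != 0)
  for (i in idx) {
    wr <- tryCatch(
      refine_w(function(x) Mod(tf_freqresp(G, x)) - 1, w[i], w[i + 1]),
      error = function(e) NA)
    if (is.na(wr)) next
    # align exact Arg at wr with the unwrapped grid phase
    ph_interp <- approx(w[c(i, i + 1)], ph[c(i, i + 1)], xout = wr)$y
    a <- Arg(tf_freqresp(G, wr)) * 180 / pi
    a <- a + 360 * round((ph_interp - a) / 360)
    p_here <- 180 + a
    if (p_here < pm_deg) {
      pm_deg <- p_here
      wgc <- wr
    }
  }

  structure(list(gain_margin_db = gm_db,
                 phase_margin_deg = pm_deg,
                 gain_crossover_hz = wgc / (2 * pi),
                 phase_crossover_hz = wpc / (2 * pi)),
            class = "margins")
}

#' @export
print.margins <- function(x, ...) {
  cat("<margins> gain margin:",
      if (is.finite(x$gain_margin_db))
        paste0(signif(x$gain_margin_db, 4), " dB at ",
               signif(x$phase_crossover_hz, 4), " Hz")
      else "Inf (no phase crossover)",
      "\n          phase margin:",
      if (is.finite(x$phase_margin_deg))
        paste0(signif(x$phase_margin_deg, 4), " deg at ",
               signif(x$gain_crossover_hz, 4), " Hz")
      else "Inf (no unity-gain crossover)",
      "\n")
  invisible(x)
}
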