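# Shared fixtures: the experimentally derived fly system and friends.

fly_gains <- function() controller_gains(10, 1)
high_gains <- function() controller_gains(60, 700)
fly_plant <- function() plant_params()          # cu_star = 4.2
fly_delay <- function() delay_model(td = 0.020) # 20 ms, Pade order 5

# Exact-delay loop frequency response, used as an independent oracle
# against the Pade-based pipeline.
exact_loop_resp <- function(gains, plant, td, omega) {
  jw <- 1i * omega
  exp(-jw * td) * (gains$kp_star * jw + gains$ki_star) /
    (jw^2 + plant$cu_star * jw)
}

# Least-squares sinusoid fit over a window: returns amplitude and phase of
# the component at frequency f in y(t) ~ a sin + b cos.
fit_sinusoid <- function(tt, y, f) {
  X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  cf <- qr.solve(X, y)
  list(amplitude = sqrt(sum(cf^2)), phase = atan2(cf[2], cf[1]))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
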