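test_that("zero-amplitude stimulus leaves the system at rest", {
  r <- simulate_hybrid(system_params(fly_gains(), sigma = 1),
                       stimulus(0, 2), sim_config(duration = 1))
  expect_true(all(r$output == 0))
  expect_true(all(r$integrator_state == 0))
  expect_length(r$saccade_times, 0)
  expect_equal(response_bound(r), 0)
})

test_that("continuous limit reproduces the linear closed-loop response", {
  # sigma = Inf collapses the hybrid system to the linear PI loop; the
  # steady-state sinusoidal response must match H(j omega)
  cfg <- sim_config(duration = 5)
  for (f in c(0.5, 2)) {
    r <- simulate_hybrid(system_params(fly_gains(), sigma = Inf),
                         stimulus(50, f), cfg)
    idx <- r$time > 3  # past the transient
    fit <- fit_sinusoid(r$time[idx], r$output[idx], f)
    H <- closed_loop_tf(fly_gains(), fly_plant(), fly_delay())
    resp <- tf_freqresp(H, 2 * pi * f)
    expect_rel_equal(fit$amplitude, 50 * Mod(resp), 0.01)
    expect_lt(abs(fit$phase - Arg(resp)), 0.01)
    expect_length(r$saccade_times, 0)
  }
})

test_that("zero threshold fires the jump map at every step", {
  cfg <- sim_config(duration = 1)
  r <- simulate_hybrid(system_params(fly_gains(), sigma = 0),
                       stimulus(50, 2), cfg)
  # a saccade at every step after the first
  expect_length(r$saccade_times, length(r$time) - 1L)
  # output is heavily bounded near zero relative to the continuous system
  ri <- simulate_hybrid(system_params(fly_gains(), sigma = Inf),
                        stimulus(50, 2), cfg)
  expect_lt(response_bound(r), 0.05 * response_bound(ri))
})

test_that("saccade count decreases as the threshold rises until smooth behavior returns", {
  cfg <- sim_config(duration = 3)
  stim <- stimulus(50, 2)
  sp <- system_params(controller_gains(2, 30), sigma = 0.5)
  counts <- vapply(c(0.5, 1.5, 3.5, 8, Inf), function(sg) {
    r <- simulate_hybrid(system_params(controller_gains(2, 30), sigma = sg),
                         stim, cfg)
    length(r$saccade_times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
  expect_identical(counts[length(counts)], 0)
})

test_that("the jump map resets integrator, plant state and trigger", {
  sigma <- 3
  r <- simulate_hybrid(system_params(fly_gains(), sigma = sigma),
                       stimulus(50, 2), sim_config(duration = 5))
  expect_gt(length(r$saccade_times), 0)
  idx <- match(round(r$saccade_times, 10), round(r$time, 10))
  expect_false(anyNA(idx))
  # at the recorded saccade sample both reset states are exactly zero
  expect_true(all(r$output[idx] == 0))
  expect_true(all(r$integrator_state[idx] == 0))
  # one step earlier the integrated error was at the threshold
  # (within one step's worth of error accumulation)
  slack <- max(abs(r$setpoint)) * r$cfg$dt * 2
  expect_true(all(abs(r$integrator_state[idx - 1]) >= sigma - slack))
  # saccade times are strictly increasing
  expect_true(all(diff(r$saccade_times) > 0))
})

test_that("halving the step changes SAE and the response bound by < 0.5%", {
  for (dt in c(1e-4, 5e-5)) {
    r <- simulate_hybrid(system_params(fly_gains(), sigma = 3),
                         stimulus(50, 2), sim_config(dt = dt, duration = 5))
    # normalize the raw SAE sum by the sample count for comparability
    val <- c(as.numeric(sae(r)) * dt, response_bound(r))
    if (dt == 1e-4) ref <- val else
      expect_true(all(abs(val - ref) / ref < 0.005))
  }
})

test_that("a delay that is not a multiple of dt is rounded with a warning", {
  expect_warning(
    simulate_hybrid(
      system_params(fly_gains(), delay = delay_model(td = 0.02005)),
      stimulus(50, 2), sim_config(dt = 1e-4, duration = 0.1)),
    "rounded")
})

test_that("unstable gains diverge only with an infinite threshold", {
  unstable <- controller_gains(10, 900)
  expect_false(is_stable(unstable, fly_plant(), fly_delay()))
  # continuous (sigma = Inf): unbounded growth, flagged and Inf bound
  r <- simulate_hybrid(system_params(unstable, sigma = Inf),
                       stimulus(50, 2), sim_config(duration = 10))
  expect_true(r$diverged)
  expect_identical(response_bound(r), Inf)
  expect_identical(as.numeric(sae(r)), Inf)
  # any finite threshold restabilizes in finite time
  for (sg in c(1, 20)) {
    rh <- simulate_hybrid(system_params(unstable, sigma = sg),
                          stimulus(50, 2), sim_config(duration = 5))
    expect_false(rh$diverged)
    expect_true(is.finite(response_bound(rh)))
  }
})

test_that("hybrid bound approaches the linear peak-to-peak as sigma grows", {
  # inside the stable region the continuous steady-state peak-to-peak is
  # 2 |H(j omega)| A; large sigma must recover it
  f <- 2
  H <- closed_loop_tf(fly_gains(), fly_plant(), fly_delay())
  lin_pp <- 2 * 50 * Mod(tf_freqresp(H, 2 * pi * f))
  r <- simulate_hybrid(system_params(fly_gains(), sigma = 1e4),
                       stimulus(50, f), sim_config(duration = 5))
  expect_rel_equal(response_bound(r), lin_pp, 0.05)
})

test_that("hybrid_bound_map separates small-sigma and large-sigma regimes", {
  cfg <- sim_config(duration = 6)
  bm <- hybrid_bound_map(c(10, 40), c(1, 700), sigma_list = c(0, 120, Inf),
                         cfg = cfg)
  expect_true(all(is.finite(bm$s_h[bm$sigma == 0])))
  # tiny threshold: uniform heavy bounding everywhere, even where the
  # continuous system is unstable
  expect_true(all(bm$s_h[bm$sigma == 0] < 5))
  expect_gt(sum(!bm$stable), 0)
  # without the saccadic supervisor, unstable pairs outgrow every stable
  # pair's steady-state bound
  inf_rows <- bm[bm$sigma == Inf, ]
  expect_gt(min(inf_rows$s_h[!inf_rows$stable]),
            2 * max(inf_rows$s_h[inf_rows$stable]))
  # for stable pairs a huge threshold already recaptures the continuous
  # steady state: sigma = 120 matches sigma = Inf
  s120 <- bm[bm$sigma == 120 & bm$stable, "s_h"]
  sInf <- bm[bm$sigma == Inf & bm$stable, "s_h"]
  expect_equal(s120, sInf, tolerance = 1e-6)
})
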