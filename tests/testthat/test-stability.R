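test_that("pole-based stability classifies the landmark systems", {
  # the fly's experimentally determined pair is stable at its 20 ms delay
  expect_true(is_stable(fly_gains(), fly_plant(), fly_delay()))
  # any positive gains are stable with no delay
  set.seed(21)
  for (i in 1:20) {
    g <- controller_gains(runif(1, 0.1, 80), runif(1, 0.1, 1000))
    expect_true(is_stable(g, fly_plant(), delay_model(td = 0)))
  }
  # 1.5x the bisected maximum stable delay is unstable
  msd <- max_stable_delay(fly_gains(), fly_plant())
  expect_false(is_stable(fly_gains(), fly_plant(),
                         delay_model(td = 1.5 * as.numeric(msd))))
})

test_that("max_stable_delay brackets, bisects and censors correctly", {
  msd <- max_stable_delay(fly_gains(), fly_plant())
  # comfortably above the fly's 20 ms
  expect_gt(as.numeric(msd), 0.020)
  expect_false(attr(msd, "censored"))
  # just below the transition stable, just above unstable
  expect_true(is_stable(fly_gains(), fly_plant(),
                        delay_model(td = as.numeric(msd) - 1e-4)))
  expect_false(is_stable(fly_gains(), fly_plant(),
                         delay_model(td = as.numeric(msd) + 1e-4)))
  # stable throughout a small bracket: censored at td_hi
  m2 <- max_stable_delay(fly_gains(), fly_plant(), td_hi = 0.01)
  expect_equal(as.numeric(m2), 0.01)
  expect_true(attr(m2, "censored"))
  # the high-ki ridge: kp = 35 tolerates more delay than kp = 10
  expect_gt(as.numeric(max_stable_delay(controller_gains(35, 700))),
            as.numeric(max_stable_delay(controller_gains(10, 700))))
})

test_that("stability is monotone in delay across a gain lattice", {
  tds <- c(0.005, 0.02, 0.04, 0.08)
  for (kp in c(5, 20, 45)) {
    for (ki in c(1, 300, 800)) {
      st <- vapply(tds, function(td) {
        is_stable(controller_gains(kp, ki), fly_plant(),
                  delay_model(td = td))
      }, logical(1))
      # once unstable, stays unstable as delay grows
      expect_true(all(diff(as.integer(st)) <= 0),
                  info = sprintf("kp=%g ki=%g: %s", kp, ki,
                                 paste(st, collapse = ",")))
    }
  }
})

test_that("stability slice at 20 ms bounds the stable gain region", {
  kp_axis <- c(2, 5, 10, 20, 35, 50, 60)
  sl <- stability_slice(0.020, kp_axis)
  # the fly pair lies under the boundary curve
  expect_gt(sl$ki_max[sl$kp_star == 10], 1)
  # points far above the boundary are unstable
  for (i in seq_len(nrow(sl))) {
    expect_false(is_stable(controller_gains(sl$kp_star[i],
                                            2 * sl$ki_max[i] + 50),
                           fly_plant(), fly_delay()))
  }
  # boundary at kp = 10 agrees with a dense ki-grid scan (step 0.5)
  ki_grid <- seq(0.5, 2000, by = 0.5)
  stable <- vapply(ki_grid, function(ki) {
    is_stable(controller_gains(10, ki), fly_plant(), fly_delay())
  }, logical(1))
  ki_scan <- max(ki_grid[stable])
  expect_lt(abs(sl$ki_max[sl$kp_star == 10] - ki_scan), 0.5)
})

test_that("stability slice degenerates to the unbounded sentinel as td -> 0", {
  sl <- stability_slice(1e-6, c(5, 30, 60), ki_hi = 2000)
  expect_true(all(is.infinite(sl$ki_max)))
})

test_that("Nyquist curve uses the exact delay and signals omega = 0", {
  expect_error(nyquist_curve(fly_gains(), omega = c(0, 1, 2)), "positive")
  expect_error(nyquist_curve(fly_gains(), omega = c(2, 1)), "ascending")

  nc <- nyquist_curve(fly_gains(), fly_plant(), fly_delay(),
                      omega = pracma::logseq(1e-2, 1e3, 500))
  oracle <- exact_loop_resp(fly_gains(), fly_plant(), 0.020, nc$omega)
  expect_equal(nc$response, oracle, tolerance = 1e-12)

  # pure proportional loop approaches kp/cu from the lower right
  ncp <- nyquist_curve(controller_gains(10, 0), fly_plant(), fly_delay(),
                       omega = c(1e-4, 1e-3))
  expect_equal(Re(ncp$response[1]), 10 / 4.2, tolerance = 1e-3)
  expect_lt(Im(ncp$response[1]), 0)
})

test_that("pole stability and exact-delay Nyquist winding agree on a lattice", {
  kps <- seq(4, 58, length.out = 8)
  kis <- seq(5, 880, length.out = 8)
  tds <- c(0.01, 0.03, 0.06)
  for (kp in kps) {
    for (ki in kis) {
      for (td in tds) {
        g <- controller_gains(kp, ki)
        d <- delay_model(td = td)
        poles_say <- is_stable(g, fly_plant(), d)
        winding <- nyquist_encirclements(g, fly_plant(), d)
        expect_identical(
          poles_say, winding == 0L,
          info = sprintf("kp=%g ki=%g td=%g winding=%d", kp, ki, td, winding))
      }
    }
  }
})

test_that("no-delay Nyquist curve never encircles -1 for positive gains", {
  set.seed(22)
  for (i in 1:10) {
    g <- controller_gains(runif(1, 0.5, 60), runif(1, 0.5, 900))
    expect_identical(nyquist_encirclements(g, fly_plant(),
                                           delay_model(td = 0)), 0L)
  }
})

test_that("a gain pair just above the 20 ms boundary crosses left of -1", {
  sl <- stability_slice(0.020, 10)
  g_above <- controller_gains(10, sl$ki_max + 20)
  expect_false(is_stable(g_above, fly_plant(), fly_delay()))
  # locate the negative-real-axis crossing of the exact-delay curve
  omega <- seq(1, 500, by = 0.01)
  resp <- exact_loop_resp(g_above, fly_plant(), 0.020, omega)
  cross <- which(diff(sign(Im(resp))) != 0 & Re(resp[-1]) < 0)
  expect_gt(length(cross), 0)
  expect_lt(min(Re(resp[cross])), -1)
})

test_that("margins match a dense-grid crossover search", {
  m <- gain_phase_margins(fly_gains(), fly_plant(), fly_delay())
  # brute-force frequency grid oracle
  G <- open_loop_tf(fly_gains(), fly_plant(), fly_delay())
  w <- seq(0.5, 200, by = 1e-4)
  resp <- tf_freqresp(G, w)
  ph <- signal::unwrap(Arg(resp)) * 180 / pi
  wpc <- w[which.min(abs(ph + 180))]
  wgc <- w[which.min(abs(Mod(resp) - 1))]
  expect_rel_equal(m$phase_crossover_hz * 2 * pi, wpc, 1e-3)
  expect_rel_equal(m$gain_crossover_hz * 2 * pi, wgc, 1e-3)
  # gain margin is the reciprocal of |G| at the phase crossover
  expect_rel_equal(10^(-m$gain_margin_db / 20),
                   Mod(tf_freqresp(G, m$phase_crossover_hz * 2 * pi)), 1e-6)

  # low-gain fly system: wide margins
  expect_gt(m$gain_margin_db, 15)
  expect_gt(m$phase_margin_deg, 90)
})

test_that("second-order delay-free loop has infinite gain margin", {
  m <- gain_phase_margins(fly_gains(), fly_plant(), delay_model(td = 0))
  expect_identical(m$gain_margin_db, Inf)
  expect_true(is.na(m$phase_crossover_hz))
  expect_true(is.finite(m$phase_margin_deg))
})

test_that("stability field and dividing surface tabulate the grid", {
  sf <- stability_field(c(5, 30), c(1, 400), c(0, 0.02, 0.05))
  expect_equal(nrow(sf), 2 * 2 * 3)
  # every delay-zero point is stable
  expect_true(all(sf$stable[sf$td == 0]))

  ds <- dividing_surface(c(5, 30), c(1, 400), td_hi = 0.3)
  expect_equal(nrow(ds), 4)
  # the surface is elevated above the zero-delay plane
  expect_true(all(ds$max_stable_delay > 0))
})
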