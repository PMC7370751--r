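test_that("closed-form period matches its definition and the simulation", {
  expect_equal(limit_cycle_period(1, 0), 1)
  expect_equal(limit_cycle_period(0.3, 0), 1)
  expect_equal(limit_cycle_period(1, 0.6), 1.25)
  expect_true(is.na(limit_cycle_period(1, 1)))        # SNIC side
  expect_gt(limit_cycle_period(1, 0.999), 20)         # period diverges
  expect_error(limit_cycle_period(-1, 0), "positive")

  # simulated crossing intervals agree with T = 1/sqrt(1 - beta*lam^2)
  # within 1% up to beta*lam^2 = 0.8
  for (lam in c(0, 0.5, sqrt(0.8))) {
    tr <- simulate_cartesian(bif_params(beta = 1, lam = lam),
                             init = c(0, -1), horizon = 30)
    mc <- measure_cycles(tr, after = 10)
    expect_lt(abs(mean(mc$cycles$period) - limit_cycle_period(1, lam)) /
                limit_cycle_period(1, lam), 0.01)
  }
})

test_that("deterministic dynamics follow the phase portrait", {
  # on the unit limit cycle at default parameters: r stays 1, period 1
  tr <- simulate_cartesian(bif_params(), init = c(1, 0), horizon = 10)
  expect_lt(max(abs(tr$r - 1)), 1e-3)
  mc <- measure_cycles(tr)
  expect_equal(mean(mc$cycles$period), 1, tolerance = 1e-3)
  expect_equal(mc$cycles$amplitude, rep(1, nrow(mc$cycles)),
               tolerance = 1e-3)

  # negative beta: stable focus, r decays to zero
  trd <- simulate_cartesian(bif_params(beta = -1), init = c(0.5, 0.5),
                            horizon = 10)
  expect_lt(trd$r[nrow(trd)], 1e-3)

  # at the SNIC point (beta = 1, lam = 1) the flow halts at theta = pi/2;
  # the approach through the quadratic bottleneck is algebraic (~1/t)
  trs <- simulate_cartesian(bif_params(beta = 1, lam = 1),
                            init = c(1, 0), horizon = 40)
  expect_equal(trs$theta[nrow(trs)], pi / 2, tolerance = 0.02)
  expect_equal(trs$r[nrow(trs)], 1, tolerance = 1e-3)
  # and the halt is persistent: theta barely moves over the last 10 units
  late <- trs$theta[trs$time > 30]
  expect_lt(diff(range(late)), 0.01)

  # monotone convergence of r to sqrt(beta) from either side
  up <- simulate_polar(bif_params(beta = 1), init = c(0.2, 0), horizon = 10)
  dn <- simulate_polar(bif_params(beta = 1), init = c(2, 0), horizon = 10)
  expect_true(all(diff(up$r) > -1e-9))
  expect_true(all(diff(dn$r) < 1e-9))
  expect_equal(up$r[nrow(up)], 1, tolerance = 1e-4)
  expect_equal(dn$r[nrow(dn)], 1, tolerance = 1e-4)
})

test_that("polar and Cartesian integrators agree from matched states", {
  p <- bif_params(beta = 1, lam = 0.5)
  tc <- simulate_cartesian(p, init = c(0.6, 0.3), horizon = 8)
  r0 <- sqrt(0.6^2 + 0.3^2); th0 <- atan2(0.3, 0.6)
  tp <- simulate_polar(p, init = c(r0, th0), horizon = 8)
  expect_lt(max(abs(tc$r - tp$r)), 1e-3)
  expect_lt(max(abs(tc$x - tp$x)), 5e-3)
})

test_that("noise-free runs are reproducible; noisy runs honour the seed", {
  p <- bif_params(beta = 1, lam = 0.3)
  a <- simulate_cartesian(p, init = c(1, 0), horizon = 5)
  b <- simulate_cartesian(p, init = c(1, 0), horizon = 5)
  expect_identical(a$x, b$x)

  pn <- bif_params(noise_sd = 0.05)
  set.seed(71); s1 <- simulate_cartesian(pn, init = c(1, 0), horizon = 2)
  set.seed(71); s2 <- simulate_cartesian(pn, init = c(1, 0), horizon = 2)
  set.seed(72); s3 <- simulate_cartesian(pn, init = c(1, 0), horizon = 2)
  expect_identical(s1$x, s2$x)
  expect_false(identical(s1$x, s3$x))
})

test_that("slow Hopf ramps delay the jump to the limit cycle", {
  # from r0 = 1e-5 the amplitude hugs zero, then jumps to sqrt(beta)
  ph <- bif_params(beta = 0, k_beta = 0.02)
  tr <- simulate_polar(ph, init = c(1e-5, pi / 2), horizon = 60)
  # still near zero well after beta crosses zero ...
  expect_lt(tr$r[which.min(abs(tr$time - 15))], 1e-3)
  # ... and on the (capped) unit cycle at the end
  expect_equal(tr$r[nrow(tr)], 1, tolerance = 0.02)
  rt <- reach_time(tr)
  expect_true(rt$reached)
  expect_gt(rt$time, 15)

  # a faster ramp reaches the cycle earlier in absolute time
  trf <- simulate_polar(bif_params(beta = 0, k_beta = 0.1),
                        init = c(1e-5, pi / 2), horizon = 60)
  expect_lt(reach_time(trf)$time, rt$time)

  # a trajectory started on the cycle at constant parameters is at the
  # cycle from the first sample
  tr0 <- simulate_cartesian(bif_params(), init = c(1, 0), horizon = 5)
  expect_equal(reach_time(tr0)$time, 0)
})

test_that("slow ramps separate SNIC and Hopf signatures", {
  # SNIC: lam rising toward 1: periods grow monotonically while the
  # amplitude stays within 5% of sqrt(beta)
  ps <- bif_params(beta = 1, lam = 0, k_lam = 0.02)
  tr <- simulate_cartesian(ps, init = c(1, 0), horizon = 45)
  mc <- measure_cycles(tr, after = 2)
  expect_true(all(diff(mc$cycles$period) > 0))
  expect_lt(max(abs(mc$cycles$amplitude - 1)), 0.05)

  # Hopf: beta rising from 0, amplitudes grow toward sqrt(beta) while the
  # period stays within 5% of 1
  ph <- bif_params(beta = 0, k_beta = 0.02)
  th <- simulate_cartesian(ph, init = c(1e-5, 0), horizon = 60)
  mh <- measure_cycles(th, after = 1)
  amps <- mh$cycles$amplitude
  expect_gt(amps[length(amps)], 0.9)
  expect_true(all(diff(amps) > -1e-6))
  expect_lt(max(abs(mh$cycles$period - 1)), 0.05)
})

test_that("stochastic onset phases disperse for Hopf but not for SNIC", {
  # 100 seeds per scenario; phases where the limit cycle is reached (Hopf)
  # or where rotation resumes (SNIC)
  hopf_ph <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    p <- bif_params(beta = 0, k_beta = 0.1, noise_sd = 0.05)
    tr <- simulate_cartesian(p, init = c(0, 0), horizon = 14)
    rt <- reach_time(tr)
    tr$theta[which.min(abs(tr$time - rt$time))]
  })
  snic_ph <- sapply(1:100, function(s) {
    set.seed(2000 + s)
    p <- bif_params(beta = 1, lam = 1, k_lam = -0.1, noise_sd = 0.05)
    tr <- simulate_polar(p, init = c(1, pi / 2), horizon = 12)
    vel <- c(diff(tr$theta_unwrapped) / diff(tr$time), 0)
    tr$theta_unwrapped[which(vel > pi)[1]] %% (2 * pi)
  })
  expect_gt(circ_var(hopf_ph), 0.5)
  expect_lt(circ_var(snic_ph), 0.2)
  # SNIC onset concentrates near the invariant-circle fixed point pi/2
  d <- abs(Arg(exp(1i * (circ_mean_rad(snic_ph) - pi / 2))))
  expect_lt(d, 1)
})
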