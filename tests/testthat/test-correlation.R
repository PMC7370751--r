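make_osc_matrix <- function(n_genes = 60, times = 1:36, period = 7,
                            noise = 0.05, seed = 1) {
  set.seed(seed)
  amps <- runif(n_genes, 0.5, 2); phs <- runif(n_genes, 0, 2 * pi)
  mu <- runif(n_genes, 6, 10)
  vals <- sapply(times, function(tt)
    mu + amps * cos(2 * pi * tt / period - phs) +
      rnorm(n_genes, 0, noise))
  expr_matrix(vals, times)
}

test_that("time-point correlation matrix behaves like Pearson on columns", {
  m <- make_osc_matrix()
  cm <- correlation_matrix(m)
  expect_equal(unname(diag(cm)), rep(1, ncol(m)))
  expect_equal(cm, t(cm), tolerance = 1e-12)

  # near-antiphase time points anti-correlate once genes are mean-centered
  cmc <- correlation_matrix(m, mean_center_genes = TRUE)
  expect_lt(cmc["7", "10"], 0)  # 3 h ~ half a 7-h cycle apart

  # shared gene means dominate uncentered correlations; centering (over a
  # course long enough to estimate the means) removes them, leaving the
  # independent fluctuations uncorrelated
  set.seed(2)
  mu <- runif(300, 5, 11)
  flat <- expr_matrix(sapply(1:10, function(i) mu + rnorm(300, 0, 0.3)),
                      1:10)
  expect_gt(correlation_matrix(flat)[1, 2], 0.8)
  expect_lt(abs(correlation_matrix(flat, mean_center_genes = TRUE)[1, 2]),
            0.2)

  tiny <- expr_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), NULL)),
                      1:2)
  expect_error(correlation_matrix(tiny), "3 shared genes")
})

test_that("correlation-line peaks sit at spline derivative roots", {
  m <- make_osc_matrix(times = 1:36, noise = 0)
  cm <- correlation_matrix(m)
  tms <- em_times(m)
  # the line of TP12 peaks at its cycle-equivalents 12, 19, 26, 33
  pk <- correlation_line_peaks(cm["12", ], tms, window = c(7, 36))
  expect_equal(pk$time, c(12, 19, 26, 33), tolerance = 0.2)
  # peak spacing equals the oscillation period
  expect_equal(diff(pk$time), rep(7, 3), tolerance = 0.3)

  # equal correlation at two adjacent time points puts the interpolated
  # peak midway between them
  line <- c(0.2, 0.3, 0.5, 0.8, 0.8, 0.5, 0.3, 0.2, 0.15, 0.1)
  pk2 <- correlation_line_peaks(line, 23:32, window = c(23, 32))
  expect_equal(pk2$time, 26.5, tolerance = 0.1)

  # a shallow bump below the line mean is not reported
  line3 <- c(1, 0.9, 0.75, 0.5, 0.3, 0.12, 0.14, 0.1, 0.05, 0)
  pk3 <- correlation_line_peaks(line3, 1:10, window = c(1, 10))
  expect_false(any(abs(pk3$time - 7) < 1))

  expect_error(correlation_line_peaks(1:3, 1:3, window = c(1, 3)),
               "4 points")
})

test_that("cycle phase mapping is linear and invertible within cycles", {
  expect_equal(assign_cycle_phase(14), 0)
  expect_equal(assign_cycle_phase(19), 300)
  expect_equal(assign_cycle_phase(17), 180)
  # inverse composed with the map is the identity on mapped times
  for (tt in c(8, 14.5, 19, 22, 30)) {
    map <- cycle_phase_map()
    cyc <- findInterval(tt, map$cycle_starts)
    expect_equal(cycle_phase_to_time(assign_cycle_phase(tt, map), cyc, map),
                 tt, tolerance = 1e-9)
  }
  expect_error(assign_cycle_phase(50), "outside")
})

test_that("arrest phase is recovered from a frozen synthetic plateau", {
  pop <- make_population_timecourse(population_spec(n_genes = 500, seed = 41))
  keep <- pop$truth$oscillating & !pop$truth$trend
  sub <- pop$mat[pop$truth$gene[keep], ]
  # map the generative cycles (7-h spacing, C4 8.5 h)
  map <- cycle_phase_map(c(pop$cycle_starts, 35.5))
  ar <- arrest_phase(sub, quiescent_times = 37:48, map = map,
                     window = c(7, 34))
  expect_true(ar$found)
  delta <- abs((ar$arrest_phase_deg - 300 + 180) %% 360 - 180)
  expect_lt(delta, 15)
  # quiescent time points correlate strongly with one another
  offdiag <- ar$quiescent_correlations[
    lower.tri(ar$quiescent_correlations)]
  expect_true(all(offdiag > 0.8))

  # an oscillatory query returns its own cycle-equivalent times
  cm <- correlation_matrix(sub)
  pk <- correlation_line_peaks(cm["16", ], em_times(sub), window = c(7, 27))
  expect_true(any(abs(pk$time - 16) < 0.5))
  expect_true(any(abs(pk$time - 23) < 0.5))  # one 7-h cycle later
})

test_that("breakpoint intersection reproduces the worked coefficients", {
  bp <- breakpoint_intersection(a1 = 5.312e-4, b1 = 13.98,
                                a2 = 0.0108, b2 = 10.07)
  expect_equal(bp$x_star, (13.98 - 10.07) / (0.0108 - 5.312e-4),
               tolerance = 1e-12)
  expect_equal(bp$x_star, 380, tolerance = 0.01)  # ~380 min
  expect_error(breakpoint_intersection(1, 0, 1, 5), "parallel")
})

test_that("breakpoint CI from error propagation has honest coverage", {
  # propagated CI vs a parametric-bootstrap oracle on one fit
  set.seed(3)
  x1 <- seq(10, 230, by = 20); x2 <- seq(450, 830, by = 20)
  d <- data.frame(
    embryo_time = c(x1, x2),
    larval_peak = c(14 + 0.0005 * x1, 10 + 0.0105 * x2) +
      rnorm(length(x1) + length(x2), 0, 0.15))
  bp <- embryo_onset_breakpoint(d)
  s1 <- summary(bp$fits[[1]])$coefficients
  s2 <- summary(bp$fits[[2]])$coefficients
  boot <- replicate(4000, {
    (rnorm(1, s1[1, 1], s1[1, 2]) - rnorm(1, s2[1, 1], s2[1, 2])) /
      (rnorm(1, s2[2, 1], s2[2, 2]) - rnorm(1, s1[2, 1], s1[2, 2]))
  })
  expect_lt(abs(bp$se - sd(boot)) / sd(boot), 0.1)

  # full-pipeline coverage on generated embryo courses: the true breakpoint
  # falls inside the 95% CI in at least 90% of replicates
  lt <- 7:36
  hits <- 0
  for (s in 1:20) {
    em <- make_embryo_timecourse(embryo_spec(seed = 100 + s))
    cm <- correlation_matrix(em$embryo, em$larval)
    pk <- sapply(seq_len(nrow(cm)), function(i) {
      p <- correlation_line_peaks(cm[i, ], lt, window = c(12.5, 20.5),
                                  method = "findpeaks")
      if (nrow(p) == 0) NA else p$time[which.max(p$value)]
    })
    b <- embryo_onset_breakpoint(
      data.frame(embryo_time = em_times(em$embryo), larval_peak = pk))
    if (380 >= b$ci[1] && 380 <= b$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
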