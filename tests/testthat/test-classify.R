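test_that("cosine fit recovers amplitude and phase of noiseless cosines", {
  t <- 10:25
  f <- fit_cosine(3 + 0.5 * cos(2 * pi * t / 7), t, period = 7)
  expect_equal(f$A, 0.5, tolerance = 1e-9)
  expect_equal(f$B, 0, tolerance = 1e-9)
  expect_equal(f$C, 0.5, tolerance = 1e-9)
  expect_equal(f$phi_deg, 0, tolerance = 1e-6)
  expect_identical(f$df, 13L)

  f90 <- fit_cosine(cos(2 * pi * t / 7 + pi / 2), t, period = 7)
  expect_equal(f90$A, 0, tolerance = 1e-9)
  expect_equal(f90$B, 1, tolerance = 1e-9)
  expect_equal(f90$phi_deg, 90, tolerance = 1e-6)

  # a log2 peak-to-trough span of 1 (linear 2-fold change) means C = 0.5:
  # the fitted cosine's continuous extremes are mean +/- C
  y2fold <- 8 + (1 / 2) * cos(2 * pi * t / 7 + 1.3)
  f2 <- fit_cosine(y2fold, t, 7)
  expect_equal(f2$C, 0.5, tolerance = 1e-9)
  expect_equal(2 * f2$C, 1, tolerance = 1e-9)  # peak-to-trough in log2

  # property: exact recovery of (C, phi) for random noiseless cosines
  set.seed(10)
  for (i in 1:25) {
    C0 <- runif(1, 0.1, 3); ph0 <- runif(1, 0, 360)
    y <- runif(1, 5, 10) + C0 * cos(2 * pi * t / 7 - ph0 * pi / 180)
    ff <- fit_cosine(y, t, 7)
    expect_equal(ff$C, C0, tolerance = 1e-8)
    expect_equal(ff$peak_phase_deg %% 360, ph0 %% 360, tolerance = 1e-5)
  }
  expect_error(fit_cosine(1:3, 1:3, 7), "4 time points")
  # period aliasing the sampling grid gives a rank-deficient design
  expect_error(fit_cosine(rnorm(8), seq(0, 7, 1), period = 1), "rank")
})

test_that("vectorized matrix fit agrees with lm on noisy traces", {
  set.seed(3)
  t <- 10:25
  y <- 7 + 0.8 * cos(2 * pi * t / 7 - 1) + rnorm(16, 0, 0.2)
  f <- fit_cosine(y, t, 7)
  fl <- lm(y ~ cos(2 * pi * t / 7) + I(-sin(2 * pi * t / 7)))
  co <- unname(coef(fl)); se <- unname(summary(fl)$coefficients[, 2])
  expect_equal(c(f$intercept, f$A, f$B), co, tolerance = 1e-10)
  expect_equal(c(f$seA, f$seB), se[2:3], tolerance = 1e-10)
})

test_that("amplitude CI propagation matches closed form and Monte Carlo", {
  # no coefficient error: degenerate interval [C, C]
  ci0 <- propagate_amplitude_ci(list(A = 1, B = 0, seA = 0, seB = 0, C = 1))
  expect_equal(c(ci0$lower, ci0$upper), c(1, 1))

  ci <- propagate_amplitude_ci(list(A = 3, B = 4, seA = 0.1, seB = 0.1, C = 5),
                               alpha = 0.01)
  expect_equal(ci$se, 0.1, tolerance = 1e-12)
  expect_equal(ci$lower, 5 - qnorm(0.995) * 0.1, tolerance = 1e-12)
  expect_equal(ci$upper, 5 + qnorm(0.995) * 0.1, tolerance = 1e-12)

  # Monte-Carlo oracle agreement within 5% of seC for C/seC >= 3
  set.seed(4)
  for (case in list(c(0.6, 0.2, 0.1, 0.1), c(2, 1, 0.3, 0.5),
                    c(1, 1, 0.2, 0.2))) {
    se_mc <- mc_amplitude_sd(case[1], case[2], case[3], case[4])
    se_an <- propagate_amplitude_ci(
      list(A = case[1], B = case[2], seA = case[3], seB = case[4],
           C = sqrt(case[1]^2 + case[2]^2)))$se
    expect_lt(abs(se_an - se_mc) / se_mc, 0.05)
  }

  # noise-dominated coefficients: lower bound below zero
  cid <- propagate_amplitude_ci(list(A = 0.05, B = 0.05, seA = 0.5, seB = 0.5,
                                     C = sqrt(2) * 0.05))
  expect_lt(cid$lower, 0)
  # zero amplitude: flagged degenerate
  expect_true(propagate_amplitude_ci(
    list(A = 0, B = 0, seA = 0.1, seB = 0.1, C = 0))$degenerate)
})

test_that("gene classification applies both cut-offs and recovers truth", {
  # amplitude cut: C just below 0.5 is rejected even with a tight CI
  t <- 10:25
  m <- expr_matrix(rbind(low = 8 + 0.49 * cos(2 * pi * t / 7),
                         high = 8 + 0.60 * cos(2 * pi * t / 7)), t)
  cl <- classify_genes(m)
  expect_false(cl$fits$oscillating[cl$fits$gene == "low"])
  expect_true(cl$fits$oscillating[cl$fits$gene == "high"])

  # synthetic population: sensitivity and specificity against ground truth
  pop <- make_population_timecourse(population_spec(n_genes = 800, seed = 21))
  cls <- classify_genes(pop$mat)
  tab <- table(pop$truth$oscillating, cls$fits$oscillating)
  sens <- tab["TRUE", "TRUE"] / sum(tab["TRUE", ])
  spcf <- tab["FALSE", "FALSE"] / sum(tab["FALSE", ])
  expect_gte(sens, 0.95)
  expect_gte(spcf, 0.99)

  # pure-noise traces pass both cut-offs at most at the nominal 1% rate
  set.seed(5)
  noise <- expr_matrix(matrix(rnorm(2000 * 16, 8, 0.2), 2000), t)
  cn <- classify_genes(noise)
  expect_lte(mean(cn$fits$oscillating), 0.01)

  expect_error(classify_genes(m, timecourse_meta(fit_window = c(30, 35))),
               "time points")
  expect_output(print(cl), "classified as oscillating")
  expect_s3_class(summary(cls), "summary.osc_class")
})

test_that("per-cycle amplitude comparison has unit slope for stable data", {
  # identical dynamics in C2 and C3 (7-h period repeats exactly): slope 1
  t <- 1:40
  set.seed(6)
  amps <- runif(40, 0.5, 2); phs <- runif(40, 0, 2 * pi)
  vals <- sapply(t, function(tt) 8 + amps * cos(2 * pi * tt / 7 - phs))
  m <- expr_matrix(vals, t)
  pca <- per_cycle_amplitudes(m)
  p23 <- pca$pairs[pca$pairs$cycle_a == "C2" & pca$pairs$cycle_b == "C3", ]
  expect_equal(p23$slope, 1, tolerance = 1e-6)
  expect_equal(p23$r, 1, tolerance = 1e-6)

  # doubling the amplitudes in C4 (generated at the C4 period) doubles the
  # cross-cycle slope
  vals3 <- sapply(t, function(tt) {
    if (tt < 27) 8 + amps * cos(2 * pi * tt / 7 - phs)
    else 8 + 2 * amps * cos(2 * pi * (tt - 27) / 8.5 - phs)
  })
  pca3 <- per_cycle_amplitudes(expr_matrix(vals3, t))
  p24 <- pca3$pairs[pca3$pairs$cycle_a == "C2" & pca3$pairs$cycle_b == "C4", ]
  expect_equal(p24$slope, 2, tolerance = 1e-6)

  # noisy stable-amplitude population: slope within [0.9, 1.1]
  pop <- make_population_timecourse(
    population_spec(n_genes = 1200, trend_fraction = 0, seed = 22))
  keep <- pop$truth$oscillating
  pcn <- per_cycle_amplitudes(pop$mat[pop$truth$gene[keep], ])
  pn23 <- pcn$pairs[pcn$pairs$cycle_a == "C2" & pcn$pairs$cycle_b == "C3", ]
  expect_gt(pn23$slope, 0.9)
  expect_lt(pn23$slope, 1.1)
})

test_that("phase agreement uses circular differences", {
  a <- c(10, 100, 250)
  pa <- phase_agreement(a, a)
  expect_equal(pa$diff_deg, c(0, 0, 0))
  expect_equal(pa$r_squared, 1)

  expect_equal(phase_agreement(10, 350)$diff_deg, 20)

  b <- (a - 30) %% 360
  pc <- phase_agreement(a, b)
  expect_equal(pc$diff_deg, rep(30, 3))
  expect_equal(pc$mean_offset_deg, 30, tolerance = 1e-9)

  # differences are invariant under a common rotation of both vectors
  set.seed(7)
  x <- runif(20, 0, 360); y <- runif(20, 0, 360)
  d0 <- phase_agreement(x, y)$diff_deg
  d1 <- phase_agreement((x + 123) %% 360, (y + 123) %% 360)$diff_deg
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_error(phase_agreement(x, y[-1]), "length")
})

test_that("tissue enrichment computes folds and exact binomial p-values", {
  # background: tissue A 10/100; oscillating subset: A 20/100 -> fold 2
  annot <- data.frame(
    gene = paste0("g", 1:100),
    tissue = c(rep("A", 10), rep("B", 90)),
    ratio = 10, qvalue = 0.01)
  osc <- c(paste0("g", 1:10),          # all 10 of tissue A
           paste0("g", 11:50))         # 40 of tissue B
  te <- tissue_enrichment(osc, annot)
  expect_equal(te$fold[te$tissue == "A"], (10 / 50) / (10 / 100))
  # p matches a direct binomial computation
  expect_equal(te$p_value[te$tissue == "A"],
               binom.test(10, 50, 0.1, alternative = "greater")$p.value)

  # equal shares give fold 1
  osc_eq <- c(paste0("g", 1:5), paste0("g", 11:55))
  te_eq <- tissue_enrichment(osc_eq, annot)
  expect_equal(te_eq$fold[te_eq$tissue == "A"], 1)

  # k = n = 10 successes at null rate 0.5: one-sided p = 2^-10
  annot2 <- data.frame(gene = paste0("h", 1:20),
                       tissue = rep(c("X", "Y"), each = 10),
                       ratio = 10, qvalue = 0.01)
  te2 <- tissue_enrichment(paste0("h", 1:10), annot2)
  expect_equal(te2$p_value[te2$tissue == "X"], 2^-10, tolerance = 1e-12)

  # the ratio/q filters are exclusive boundaries
  annot3 <- annot
  annot3$ratio[1] <- 5      # not > 5: drops out of the background
  te3 <- tissue_enrichment(osc, annot3)
  expect_equal(sum(te3$n_background), 99)
})

test_that("circular phase density wraps correctly at 0/360", {
  # uniform phases: flat density
  ph <- seq(0, 359, by = 1)
  d <- circular_phase_density(ph, bw = 20)
  expect_lt(diff(range(d$y)) / mean(d$y), 0.01)
  expect_equal(d$y[1], d$y[length(d$y)], tolerance = 1e-6)

  # point mass just below 360 leaks density across the wrap
  d2 <- circular_phase_density(rep(359, 50), bw = 10)
  at5 <- d2$y[which.min(abs(d2$x - 5))]
  at180 <- d2$y[which.min(abs(d2$x - 180))]
  expect_gt(at5, 100 * max(at180, 1e-12))

  # agreement with a direct wrapped-kernel oracle
  set.seed(8)
  ph3 <- runif(200, 0, 360)
  d3 <- circular_phase_density(ph3, bw = 15, n = 181)
  oracle <- wrapped_kernel_density(ph3, d3$x, bw = 15)
  expect_equal(d3$y, oracle, tolerance = 0.02)
  expect_error(circular_phase_density(numeric(0)), "empty")
})
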